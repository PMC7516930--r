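# The INF node-influence indicator. Each node i collects the energy
# sum over its generalized neighbourhood {j : 0 < d_ij <= R} of
# w_ij / k_j (with a d_ij^2 distance factor whose placement only matters for
# R > 1), where w_ij is the connecting edge weight (1 for unweighted input
# and for non-adjacent pairs) and k_j the neighbour's degree. The raw sum is
# mapped to (0, 1) by the logistic function 1/(1 + exp(-raw)); the logistic
# map is strictly monotone, so raw and logistic mode induce the same ranking.

.infRaw <- function(g, R, distanceWeight, kOf = NULL, wMat = NULL) {
  n <- vcount(g)
  d <- distances(g, weights = NA)
  k <- if (is.null(kOf)) degree(g) else kOf
  if (is.null(wMat)) {
    wMat <- as_adjacency_matrix(g, attr =
      if ("weight" %in% edge_attr_names(g)) "weight" else NULL, sparse = TRUE)
  }
  vapply(seq_len(n), function(i) {
    j <- which(d[i, ] > 0 & d[i, ] <= R & is.finite(d[i, ]))
    if (!length(j)) return(0)
    w <- ifelse(d[i, j] == 1, as.numeric(wMat[i, j]), 1)
    f <- if (distanceWeight == "denominator") 1 / d[i, j]^2 else d[i, j]^2
    sum(f * w / k[j], na.rm = FALSE)
  }, numeric(1))
}

.infNormalize <- function(raw, normalization) {
  if (normalization == "logistic") 1 / (1 + exp(-raw)) else raw
}

#' INF node influence on a monolayer network
#'
#' Scores every node by the degree-discounted weight of its neighbourhood
#' within \code{R} hops: \eqn{raw(i) = \sum_{0 < d_{ij} \le R} w_{ij}/k_j}
#' (times a \eqn{d_{ij}^2} factor for \code{R > 1}, placed per
#' \code{distanceWeight}; at the default \code{R = 1} all distances are 1 and
#' the factor is moot). With \code{normalization = "logistic"} the raw sum is
#' mapped through \eqn{1/(1+e^{-raw})}, so scores lie in (0, 1), isolated
#' nodes score 0.5 and any node with a neighbour scores above 0.5.
#'
#' @param g an igraph; edge weights are used as \eqn{w_{ij}} when present.
#' @param R positive integer truncation radius (default 1).
#' @param normalization \code{"logistic"} (default) or \code{"raw"}.
#' @param distanceWeight where the \eqn{d_{ij}^2} factor goes for
#'   \code{R > 1}: \code{"denominator"} (default, gravity-style decay) or
#'   \code{"numerator"}.
#' @return a [ScoreTable-class].
#' @examples
#' g <- kiteNetwork()
#' scores(infScores(g))["Diane"]   # 0.8273
#' @export
infScores <- function(g, R = 1L,
                      normalization = c("logistic", "raw"),
                      distanceWeight = c("denominator", "numerator")) {
  normalization <- match.arg(normalization)
  distanceWeight <- match.arg(distanceWeight)
  if (!is.numeric(R) || R < 1) stop("R must be a positive integer")
  if (normalization == "logistic" && any(degree(g) == 0))
    message("isolated node(s) present: their logistic INF is 0.5")
  raw <- .infRaw(g, R, distanceWeight)
  .scoreTable("inf",
              list(R = as.integer(R), normalization = normalization,
                   distanceWeight = distanceWeight),
              .infNormalize(raw, normalization), V(g)$name)
}

#' INF node influence on a multilayer network
#'
#' Evaluates the INF sum over the supra-graph: at the default \code{R = 1}
#' every replica collects \eqn{w_{ij}/k_j} from each neighbour reached
#' through an intra-layer or an inter-layer edge, both on equal footing. The
#' neighbour degree convention is set by \code{degreeMode}: \code{"supra"}
#' (default) counts a replica's intra-layer plus inter-layer incident edges,
#' so the computation equals the monolayer INF of the supra-graph;
#' \code{"intra"} uses only the neighbour's degree within its own layer
#' (neighbours with no intra-layer edges then contribute nothing).
#'
#' @param m a [MultilayerNetwork-class].
#' @param R positive integer truncation radius (default 1), measured in supra-graph hops.
#' @param normalization \code{"logistic"} (default) or \code{"raw"}.
#' @param degreeMode \code{"supra"} (default) or \code{"intra"}.
#' @param aggregate when TRUE, sum the raw scores of a physical node's
#'   replicas across layers before normalizing, returning one score per
#'   physical node instead of per replica.
#' @return a [ScoreTable-class] over \code{"layer::node"} replicas (or over
#'   physical nodes when \code{aggregate = TRUE}).
#' @export
infScoresMultilayer <- function(m, R = 1L,
                                normalization = c("logistic", "raw"),
                                degreeMode = c("supra", "intra"),
                                aggregate = FALSE) {
  normalization <- match.arg(normalization)
  degreeMode <- match.arg(degreeMode)
  if (!is.numeric(R) || R < 1) stop("R must be a positive integer")
  empty <- vapply(layers(m), function(g) vcount(g) == 0L, logical(1))
  if (any(empty))
    warning(sprintf("skipping empty layer(s): %s",
                    paste(layerNames(m)[empty], collapse = ", ")))
  sg <- .supraGraph(m)
  kOf <- if (degreeMode == "supra") {
    degree(sg)
  } else {
    intra <- subgraph.edges(sg, E(sg)[E(sg)$type == "intra"],
                            delete.vertices = FALSE)
    ki <- degree(intra)
    ki[ki == 0] <- Inf   # inter-only replicas contribute nothing
    ki
  }
  raw <- .infRaw(sg, R, "denominator", kOf = kOf)
  names(raw) <- V(sg)$name
  if (aggregate) {
    phys <- V(sg)$node
    raw <- tapply(raw, phys, sum)
    raw <- raw[unique(phys)]   # keep first-appearance order
  }
  .scoreTable("inf_multilayer",
              list(R = as.integer(R), normalization = normalization,
                   degreeMode = degreeMode, aggregate = aggregate),
              .infNormalize(as.numeric(raw), normalization), names(raw))
}

#' Top-k nodes of a score table
#'
#' The k highest-scoring nodes in descending score order; ties are broken by
#' ascending node identifier, so the selection is deterministic.
#'
#' @param scoreTable a [ScoreTable-class].
#' @param k positive integer, at most the number of scored nodes.
#' @return character vector of k node identifiers.
#' @export
topK <- function(scoreTable, k) {
  s <- scores(scoreTable)
  if (!is.numeric(k) || k < 1) stop("k must be a positive integer")
  if (k > length(s))
    stop(sprintf("k = %d exceeds the %d scored nodes", k, length(s)))
  ord <- order(-s, names(s), method = "radix")
  names(s)[ord][seq_len(k)]
}
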