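# Validation experiments: Kendall tau agreement with SIR ground truth,
# targeted node-removal fragmentation curves, and top-k seeding spread
# curves.

# Registry of indicator labels usable in benchmark experiments.
.indicatorFun <- function(method) {
  switch(method,
    dc      = function(g) degreeCentrality(g),
    bc      = function(g) betweennessCentrality(g),
    cc      = function(g) closenessCentrality(g),
    ec      = function(g) eigenvectorCentrality(g),
    pr      = function(g) pagerank(g),
    katz    = function(g) katzCentrality(g),
    cluster = function(g) clusteringCoefficient(g),
    gr      = function(g) gravityCentrality(g),
    grplus  = function(g) gravityPlus(g),
    lgr     = function(g) localGravity(g),
    inf     = function(g) infScores(g),
    stop(sprintf("unknown indicator '%s'", method))
  )
}

#' Kendall tau-a rank agreement between two aligned sequences
#'
#' \eqn{\tau = (N_c - N_d) / (n(n-1)/2)} where \eqn{N_c} and \eqn{N_d} count
#' concordant and discordant pairs. Pairs tied in either sequence are neither
#' concordant nor discordant, and the denominator stays \eqn{n(n-1)/2}, so
#' ties attenuate \eqn{|\tau|} (the tau-a convention, not tau-b).
#'
#' @param x,y numeric sequences of equal length n >= 2, aligned by node.
#' @param indicator optional label stored in the result.
#' @param protocol optional named list recording how the reference sequence
#'   \code{x} was produced.
#' @return a [RankingComparison-class].
#' @examples
#' tauValue(kendallTau(1:3, 3:1))   # -1
#' @export
kendallTau <- function(x, y, indicator = "", protocol = list()) {
  if (length(x) != length(y))
    stop("x and y must have the same length")
  n <- length(x)
  if (n < 2L) stop("need at least two observations")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  s <- sx * sy
  up <- upper.tri(s)
  nc <- sum(s[up] > 0)
  nd <- sum(s[up] < 0)
  new("RankingComparison", indicator = indicator,
      tau = (nc - nd) / (n * (n - 1) / 2),
      nConcordant = nc, nDiscordant = nd, n = as.integer(n),
      protocol = protocol)
}

#' SIR ground-truth spreading influence of every node
#'
#' Estimates each node's spreading influence \eqn{P(i) = N_R/N} by seeding it
#' alone in \code{nRuns} independent SIR simulations. This is the standard
#' reference sequence for [kendallTau()] comparisons of indicators.
#'
#' @param g an igraph.
#' @param beta per-contact infection probability (default 0.35).
#' @param gamma per-step recovery probability (default 1).
#' @param nRuns independent simulations per node (default 1000).
#' @param rngSeed optional integer seed for bit-exact replay.
#' @return a [ScoreTable-class] of mean \eqn{P(i)} per node.
#' @export
sirGroundTruth <- function(g, beta = 0.35, gamma = 1, nRuns = 1000L,
                           rngSeed = NULL) {
  .checkSIRParams(beta, gamma)
  if (!is.null(rngSeed)) set.seed(rngSeed)
  prep <- .sirPrep(g, beta)
  p <- vapply(seq_len(vcount(g)), function(i) {
    tot <- 0
    for (r in seq_len(nRuns))
      tot <- tot + length(.sirOnce(prep, i, gamma)$recovered)
    tot / nRuns / prep$n
  }, numeric(1))
  .scoreTable("sir_ground_truth",
              list(beta = beta, gamma = gamma, nRuns = as.integer(nRuns),
                   rngSeed = rngSeed), p, V(g)$name)
}

#' Kendall tau of several indicators against SIR ground truth
#'
#' Computes one SIR ground-truth sequence and the tau-a agreement of each
#' requested indicator with it.
#'
#' @param g an igraph.
#' @param indicators character vector of indicator labels among
#'   \code{dc, bc, cc, ec, pr, katz, cluster, gr, grplus, lgr, inf}.
#' @param beta,gamma,nRuns,rngSeed SIR protocol, as in [sirGroundTruth()].
#' @param groundTruth optional precomputed [ScoreTable-class] to reuse.
#' @return named list of [RankingComparison-class], one per indicator.
#' @export
tauBenchmark <- function(g, indicators = c("dc", "bc", "cc", "lgr", "inf"),
                         beta = 0.35, gamma = 1, nRuns = 1000L,
                         rngSeed = NULL, groundTruth = NULL) {
  if (is.null(groundTruth))
    groundTruth <- sirGroundTruth(g, beta, gamma, nRuns, rngSeed)
  ref <- scores(groundTruth)
  protocol <- methodParams(groundTruth)
  out <- lapply(indicators, function(mth) {
    st <- .indicatorFun(mth)(g)
    kendallTau(ref, scores(st)[names(ref)], indicator = mth,
               protocol = protocol)
  })
  names(out) <- indicators
  out
}

#' Targeted node-removal fragmentation curve
#'
#' Removes nodes one at a time in descending score order (static order from
#' the intact graph; ties broken by ascending node identifier), recording the
#' number of connected components after each removal. The curve starts at the
#' intact graph's component count, rises to a maximum once all edges are
#' gone, then falls to 0 when the last node is deleted.
#'
#' @param g an igraph.
#' @param scoreTable a [ScoreTable-class] covering all nodes of \code{g}.
#' @param recompute when TRUE, rescore the remaining graph before every
#'   removal (adaptive order) using the indicator registry entry matching
#'   \code{methodName(scoreTable)}.
#' @return data.frame with columns \code{step} (0..N), \code{removed} (NA for
#'   step 0) and \code{subgraphs}; attributes \code{indicator} and
#'   \code{tieRule}.
#' @export
removalCurve <- function(g, scoreTable, recompute = FALSE) {
  s <- scores(scoreTable)
  if (!all(V(g)$name %in% names(s)))
    stop("scoreTable must cover every node of the graph")
  n <- vcount(g)
  removed <- character(n)
  counts <- integer(n)
  work <- g
  if (!recompute) {
    ord <- names(s)[order(-s[V(g)$name], V(g)$name, method = "radix")]
  }
  for (i in seq_len(n)) {
    victim <- if (recompute) {
      sw <- scores(.indicatorFun(methodName(scoreTable))(work))
      names(sw)[order(-sw, names(sw), method = "radix")][1]
    } else ord[i]
    work <- delete_vertices(work, victim)
    removed[i] <- victim
    counts[i] <- connectedComponentCount(work)
  }
  out <- data.frame(step = 0:n, removed = c(NA_character_, removed),
                    subgraphs = c(connectedComponentCount(g), counts),
                    stringsAsFactors = FALSE)
  attr(out, "indicator") <- methodName(scoreTable)
  attr(out, "tieRule") <- "descending score, ties by ascending node id"
  attr(out, "recompute") <- recompute
  out
}

#' Top-k seeding spread curve
#'
#' For each indicator and each seed fraction k/N, seeds the indicator's top-k
#' node set simultaneously and reports the mean final recovered count over
#' repeated SIR runs at \eqn{\beta = \mathrm{betaRatio} \cdot \beta_c}
#' (clipped to [0, 1]). Common random numbers (one sub-seed per run index,
#' derived from \code{rngSeed}) make the whole table bit-reproducible and
#' comparable across indicators.
#'
#' @param g an igraph.
#' @param indicators character vector of indicator labels.
#' @param kFractions seed-set sizes as fractions of N (default 0.05..0.20);
#'   each fraction must give at least 1 and at most N seeds.
#' @param betaRatio multiple of the epidemic threshold used as beta
#'   (default 1.5).
#' @param gamma per-step recovery probability (default 1).
#' @param nRuns SIR runs per cell (default 1000).
#' @param rngSeed integer seed (default 1).
#' @return data.frame with columns \code{indicator}, \code{kFraction},
#'   \code{k}, \code{meanRecovered}; attributes \code{beta},
#'   \code{betaRatio}, \code{nRuns}, \code{rngSeed}.
#' @export
topkSpread <- function(g, indicators = c("dc", "bc", "cc", "lgr", "inf"),
                       kFractions = c(0.05, 0.1, 0.15, 0.2),
                       betaRatio = 1.5, gamma = 1, nRuns = 1000L,
                       rngSeed = 1L) {
  n <- vcount(g)
  ks <- pmax(1L, as.integer(round(kFractions * n)))
  if (any(ks > n)) stop("k exceeds the number of nodes")
  beta <- min(1, max(0, betaRatio * epidemicThreshold(g)))
  prep <- .sirPrep(g, beta)
  rows <- list()
  for (mth in indicators) {
    st <- .indicatorFun(mth)(g)
    for (j in seq_along(ks)) {
      seeds <- match(topK(st, ks[j]), V(g)$name)
      tot <- 0
      for (r in seq_len(nRuns)) {
        set.seed(rngSeed + r)   # common random numbers across cells
        tot <- tot + length(.sirOnce(prep, seeds, gamma)$recovered)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = mth, kFraction = kFractions[j], k = ks[j],
        meanRecovered = tot / nRuns, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "beta") <- beta
  attr(out, "betaRatio") <- betaRatio
  attr(out, "nRuns") <- as.integer(nRuns)
  attr(out, "rngSeed") <- as.integer(rngSeed)
  out
}
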