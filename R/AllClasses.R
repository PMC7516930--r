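setOldClass("igraph")

#' MultilayerNetwork: a family of layer graphs plus inter-layer couplings
#'
#' Represents a general multilayer network \eqn{M = (G, C)}: an ordered family
#' of layer graphs \eqn{G_\alpha} sharing one global node-identifier space,
#' together with a set \eqn{C} of weighted inter-layer edges joining node
#' replicas in different layers. Layers may hold different node sets (the
#' general model, of which a multiplex is the special case with identical node
#' sets and replica-only couplings). The replica \code{(layer, node)} is the
#' unit of analysis: supra-adjacency rows, multilayer INF scores and SIR states
#' are all indexed by replicas, labelled \code{"layer::node"}.
#'
#' @slot layers named list of undirected \code{igraph} objects, one per layer,
#'   in first-appearance order; names are the layer labels.
#' @slot interEdges data.frame with columns \code{node1, layer1, node2,
#'   layer2, weight}: inter-layer couplings between existing replicas,
#'   \code{layer1 != layer2}, weights > 0.
#'
#' @seealso [readMultiplex()], [supraAdjacency()], [infScoresMultilayer()]
#' @export
setClass("MultilayerNetwork",
  representation(layers = "list", interEdges = "data.frame"))

setValidity("MultilayerNetwork", function(object) {
  msgs <- character()
  if (length(object@layers) < 1L)
    msgs <- c(msgs, "a MultilayerNetwork needs at least one layer")
  if (!all(vapply(object@layers, inherits, logical(1), "igraph")))
    msgs <- c(msgs, "every layer must be an igraph object")
  ln <- names(object@layers)
  if (is.null(ln) || anyDuplicated(ln) || any(!nzchar(ln)))
    msgs <- c(msgs, "layers must carry unique non-empty names")
  ie <- object@interEdges
  need <- c("node1", "layer1", "node2", "layer2", "weight")
  if (!all(need %in% names(ie))) {
    msgs <- c(msgs, sprintf("interEdges must have columns %s",
                            paste(need, collapse = ", ")))
  } else if (nrow(ie) > 0L) {
    if (any(ie$layer1 == ie$layer2))
      msgs <- c(msgs, "inter-layer edges must join two distinct layers")
    if (any(!(ie$layer1 %in% ln)) || any(!(ie$layer2 %in% ln)))
      msgs <- c(msgs, "inter-layer edge references an unknown layer label")
    if (any(!is.finite(ie$weight)) || any(ie$weight <= 0))
      msgs <- c(msgs, "inter-layer weights must be positive and finite")
    for (k in seq_len(nrow(ie))) {
      if (ie$layer1[k] %in% ln &&
          !(ie$node1[k] %in% V(object@layers[[ie$layer1[k]]])$name))
        msgs <- c(msgs, sprintf("replica (%s, %s) not present in its layer",
                                ie$node1[k], ie$layer1[k]))
      if (ie$layer2[k] %in% ln &&
          !(ie$node2[k] %in% V(object@layers[[ie$layer2[k]]])$name))
        msgs <- c(msgs, sprintf("replica (%s, %s) not present in its layer",
                                ie$node2[k], ie$layer2[k]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ScoreTable: one centrality indicator evaluated on one network
#'
#' Holds a node -> score map for a single indicator together with the method
#' name and the parameter record needed to reproduce it (radius, damping,
#' normalization mode, ...). Scores cover every node of the input exactly once
#' and are finite.
#'
#' @slot method short method label, e.g. \code{"inf"}, \code{"dc"}.
#' @slot params named list of the parameters the scores were computed with.
#' @slot scores named numeric vector, one finite score per node.
#'
#' @seealso [scores()], [topK()], [infScores()]
#' @export
setClass("ScoreTable",
  representation(method = "character", params = "list", scores = "numeric"))

setValidity("ScoreTable", function(object) {
  msgs <- character()
  if (length(object@method) != 1L) msgs <- c(msgs, "method must be length 1")
  s <- object@scores
  if (is.null(names(s)) || anyDuplicated(names(s)))
    msgs <- c(msgs, "scores must be uniquely named by node")
  if (length(s) && any(!is.finite(s)))
    msgs <- c(msgs, "scores must be finite")
  if (length(msgs)) msgs else TRUE
})

#' SIROutcome: aggregated results of repeated SIR spreading runs
#'
#' Per-run final recovered counts and step counts from \code{nRuns}
#' independent discrete-time SIR simulations started from one seed set, plus
#' the configuration used. The seed always ends recovered, so every per-run
#' recovered count is at least the seed-set size.
#'
#' @slot recovered integer vector, final recovered count of each run.
#' @slot iterations integer vector, synchronous steps taken by each run.
#' @slot nNodes total node (or replica) count N of the simulated network.
#' @slot config named list recording beta, gamma, nRuns, seeds and rngSeed.
#'
#' @seealso [spreadEstimate()], [meanRecovered()], [spreadProbability()]
#' @export
setClass("SIROutcome",
  representation(recovered = "integer", iterations = "integer",
                 nNodes = "integer", config = "list"))

setValidity("SIROutcome", function(object) {
  msgs <- character()
  if (length(object@recovered) != length(object@iterations))
    msgs <- c(msgs, "recovered and iterations must have one entry per run")
  if (length(object@recovered) &&
      (any(object@recovered < 1L) || any(object@recovered > object@nNodes)))
    msgs <- c(msgs, "each run must recover between 1 and N nodes")
  if (length(msgs)) msgs else TRUE
})

#' RankingComparison: Kendall tau agreement between two node rankings
#'
#' The tau-a statistic \eqn{\tau = (N_c - N_d) / (n(n-1)/2)} between an
#' indicator's scores and a reference sequence (typically SIR mean spread).
#' Tied pairs in either sequence are neither concordant nor discordant, so
#' ties attenuate \eqn{|\tau|} — the denominator stays \eqn{n(n-1)/2}.
#'
#' @slot indicator label of the indicator compared against the reference.
#' @slot tau the tau-a value in [-1, 1].
#' @slot nConcordant,nDiscordant concordant / discordant pair counts.
#' @slot n sequence length.
#' @slot protocol named list recording how the reference was produced
#'   (beta, gamma, runs, rngSeed), when known.
#'
#' @seealso [kendallTau()], [tauBenchmark()]
#' @export
setClass("RankingComparison",
  representation(indicator = "character", tau = "numeric",
                 nConcordant = "numeric", nDiscordant = "numeric",
                 n = "integer", protocol = "list"))

setValidity("RankingComparison", function(object) {
  msgs <- character()
  if (length(object@tau) != 1L || !is.finite(object@tau) ||
      abs(object@tau) > 1 + 1e-12)
    msgs <- c(msgs, "tau must be a single value in [-1, 1]")
  if (object@nConcordant + object@nDiscordant >
      object@n * (object@n - 1L) / 2 + 1e-9)
    msgs <- c(msgs, "Nc + Nd cannot exceed n(n-1)/2")
  if (length(msgs)) msgs else TRUE
})

#' NetworkSummary: the standard descriptive statistics of a network
#'
#' The summary columns reported for benchmark networks: node and edge counts,
#' average degree \eqn{\langle k\rangle}, average shortest path length
#' \eqn{\langle d\rangle}, average local clustering, degree assortativity,
#' degree heterogeneity \eqn{|H| = \langle k^2\rangle/\langle k\rangle^2}
#' and the SIR epidemic threshold \eqn{\beta_c}. For multilayer networks the
#' statistics are computed on the supra-graph and the layer / intra- /
#' inter-layer edge counts are filled in.
#'
#' @slot nNodes,nEdges,nLayers,nIntraEdges,nInterEdges integer counts
#'   (layer fields are \code{NA} for monolayer input).
#' @slot avgDegree,avgPath,avgClustering,assortativity,heterogeneity,epidemicThreshold
#'   the named statistics; \code{NA} where undefined (e.g. assortativity of a
#'   regular graph).
#' @slot pathOnLargestComponent TRUE when the graph is disconnected and
#'   \code{avgPath} was computed on the largest component only.
#'
#' @seealso [networkSummary()]
#' @export
setClass("NetworkSummary",
  representation(nNodes = "integer", nEdges = "integer",
                 nLayers = "integer", nIntraEdges = "integer",
                 nInterEdges = "integer",
                 avgDegree = "numeric", avgPath = "numeric",
                 avgClustering = "numeric", assortativity = "numeric",
                 heterogeneity = "numeric", epidemicThreshold = "numeric",
                 pathOnLargestComponent = "logical"))
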