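#' Extract the node -> score map from a ScoreTable
#'
#' @param x a [ScoreTable-class].
#' @return named numeric vector of scores.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "ScoreTable", function(x) x@scores)

#' Method label of a ScoreTable
#' @param x a [ScoreTable-class].
#' @return single character label.
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname methodName
#' @export
setMethod("methodName", "ScoreTable", function(x) x@method)

#' Parameter record of a ScoreTable
#' @param x a [ScoreTable-class].
#' @return named list of parameters.
#' @export
setGeneric("methodParams", function(x) standardGeneric("methodParams"))

#' @rdname methodParams
#' @export
setMethod("methodParams", "ScoreTable", function(x) x@params)

#' Layer graphs of a MultilayerNetwork
#' @param x a [MultilayerNetwork-class].
#' @return named list of igraph layers, in layer order.
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))

#' @rdname layers
#' @export
setMethod("layers", "MultilayerNetwork", function(x) x@layers)

#' Layer labels of a MultilayerNetwork
#' @param x a [MultilayerNetwork-class].
#' @return character vector of layer names in layer order.
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname layerNames
#' @export
setMethod("layerNames", "MultilayerNetwork", function(x) names(x@layers))

#' Number of layers
#' @param x a [MultilayerNetwork-class].
#' @return integer layer count L.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname nLayers
#' @export
setMethod("nLayers", "MultilayerNetwork", function(x) length(x@layers))

#' Inter-layer coupling edges
#' @param x a [MultilayerNetwork-class].
#' @return data.frame with columns node1, layer1, node2, layer2, weight.
#' @export
setGeneric("interlayerEdges", function(x) standardGeneric("interlayerEdges"))

#' @rdname interlayerEdges
#' @export
setMethod("interlayerEdges", "MultilayerNetwork", function(x) x@interEdges)

#' Mean final recovered count of an SIR outcome
#' @param x a [SIROutcome-class].
#' @return mean of the per-run recovered counts.
#' @export
setGeneric("meanRecovered", function(x) standardGeneric("meanRecovered"))

#' @rdname meanRecovered
#' @export
setMethod("meanRecovered", "SIROutcome", function(x) mean(x@recovered))

#' Mean number of synchronous steps of an SIR outcome
#' @param x a [SIROutcome-class].
#' @return mean of the per-run step counts.
#' @export
setGeneric("meanIterations", function(x) standardGeneric("meanIterations"))

#' @rdname meanIterations
#' @export
setMethod("meanIterations", "SIROutcome", function(x) mean(x@iterations))

#' Spreading influence P(i) = N_R / N of an SIR outcome
#' @param x a [SIROutcome-class].
#' @return mean recovered fraction, in (0, 1].
#' @export
setGeneric("spreadProbability", function(x) standardGeneric("spreadProbability"))

#' @rdname spreadProbability
#' @export
setMethod("spreadProbability", "SIROutcome",
          function(x) mean(x@recovered) / x@nNodes)

#' Number of runs aggregated in an SIR outcome
#' @param x a [SIROutcome-class].
#' @return integer run count.
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname nRuns
#' @export
setMethod("nRuns", "SIROutcome", function(x) length(x@recovered))

#' Kendall tau value of a ranking comparison
#' @param x a [RankingComparison-class].
#' @return the tau-a value.
#' @export
setGeneric("tauValue", function(x) standardGeneric("tauValue"))

#' @rdname tauValue
#' @export
setMethod("tauValue", "RankingComparison", function(x) x@tau)

#' Summary statistics of a network
#'
#' Computes the standard descriptive columns for a monolayer graph or, for a
#' multilayer network, for its supra-graph (layer and intra-/inter-layer edge
#' counts are then also reported).
#'
#' @param x an igraph or a [MultilayerNetwork-class].
#' @param ... unused.
#' @return a [NetworkSummary-class].
#' @export
setGeneric("networkSummary", function(x, ...) standardGeneric("networkSummary"))

#' Supra-adjacency matrix of a multilayer network
#'
#' Assembles the block matrix with the layer adjacencies \eqn{A_1 \dots A_L}
#' on the diagonal and the inter-layer couplings \eqn{I_{\alpha\beta}} in the
#' off-diagonal blocks. Rows and columns are indexed replica-wise in
#' layer-major order (all replicas of layer 1 in that layer's node order,
#' then layer 2, ...), with dimnames \code{"layer::node"}.
#'
#' @param x a [MultilayerNetwork-class].
#' @param ... unused.
#' @return a sparse symmetric numeric matrix of size N x N where N is the
#'   total replica count.
#' @export
setGeneric("supraAdjacency", function(x, ...) standardGeneric("supraAdjacency"))

# show methods ---------------------------------------------------------------

#' @describeIn MultilayerNetwork-class compact display
#' @param object object to display.
#' @export
setMethod("show", "MultilayerNetwork", function(object) {
  nV <- sum(vapply(object@layers, vcount, numeric(1)))
  nA <- sum(vapply(object@layers, ecount, numeric(1)))
  cat(sprintf("MultilayerNetwork: %d layer(s), %d node replicas\n",
              length(object@layers), nV))
  cat(sprintf("  intra-layer edges |E_A| = %d, inter-layer edges |E_C| = %d\n",
              nA, nrow(object@interEdges)))
  for (nm in names(object@layers))
    cat(sprintf("  layer %-12s %4d nodes %5d edges\n", nm,
                vcount(object@layers[[nm]]), ecount(object@layers[[nm]])))
})

#' @describeIn ScoreTable-class compact display (top scores first)
#' @param object object to display.
#' @export
setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable <%s> over %d nodes\n", object@method,
              length(object@scores)))
  if (length(object@params)) {
    pv <- vapply(object@params, function(p) paste(format(p), collapse = ","),
                 character(1))
    cat("  params:", paste(names(pv), pv, sep = "=", collapse = ", "), "\n")
  }
  s <- sort(object@scores, decreasing = TRUE)
  shown <- head(s, 5L)
  cat("  top:", paste(sprintf("%s=%.4f", names(shown), shown),
                      collapse = ", "),
      if (length(s) > 5L) "..." else "", "\n")
})

#' @describeIn SIROutcome-class compact display
#' @param object object to display.
#' @export
setMethod("show", "SIROutcome", function(object) {
  cat(sprintf(
    "SIROutcome: %d runs on N=%d | mean recovered %.4f (P = %.4f), mean steps %.4f\n",
    length(object@recovered), object@nNodes, mean(object@recovered),
    mean(object@recovered) / object@nNodes, mean(object@iterations)))
})

#' @describeIn RankingComparison-class compact display
#' @param object object to display.
#' @export
setMethod("show", "RankingComparison", function(object) {
  cat(sprintf("RankingComparison <%s>: tau = %.4f (Nc = %d, Nd = %d, n = %d)\n",
              object@indicator, object@tau, as.integer(object@nConcordant),
              as.integer(object@nDiscordant), object@n))
})

#' @describeIn NetworkSummary-class tabular display
#' @param object object to display.
#' @export
setMethod("show", "NetworkSummary", function(object) {
  cat("NetworkSummary\n")
  if (!is.na(object@nLayers))
    cat(sprintf("  |L| = %d  |E_A| = %d  |E_C| = %d\n", object@nLayers,
                object@nIntraEdges, object@nInterEdges))
  cat(sprintf("  |V| = %d  |E| = %d\n", object@nNodes, object@nEdges))
  cat(sprintf("  <k> = %.4f  <d> = %.4f%s\n", object@avgDegree, object@avgPath,
              if (isTRUE(object@pathOnLargestComponent))
                " (largest component)" else ""))
  cat(sprintf("  |C| = %.4f  r = %s  |H| = %.4f  beta_c = %s\n",
              object@avgClustering,
              ifelse(is.na(object@assortativity), "NA",
                     sprintf("%.4f", object@assortativity)),
              object@heterogeneity,
              ifelse(is.na(object@epidemicThreshold), "NA",
                     sprintf("%.4f", object@epidemicThreshold))))
})
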