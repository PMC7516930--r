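# Shared graph machinery: hop distances, components, k-shell, supra-graph
# assembly and summary statistics. Distances are always hop counts (unit edge
# length): edge weights enter the influence and spreading computations as
# w_ij factors, never as path lengths.

#' Hop distances from one source node
#'
#' Breadth-first shortest path lengths (edge weights ignored) from
#' \code{source} to every reachable node, optionally truncated at
#' \code{cutoff} hops. Unreachable nodes are absent from the result;
#' \code{d(source, source) = 0}.
#'
#' @param g an igraph.
#' @param source a vertex name present in \code{g}.
#' @param cutoff optional maximum hop distance to keep.
#' @return named numeric vector of hop distances.
#' @export
shortestPathLengths <- function(g, source, cutoff = NULL) {
  if (!(source %in% V(g)$name))
    stop(sprintf("unknown source node '%s'", source))
  d <- distances(g, v = source, weights = NA, mode = "out")[1, ]
  d <- d[is.finite(d)]
  if (!is.null(cutoff)) d <- d[d <= cutoff]
  d
}

#' Number of connected components
#'
#' Weakly connected components; isolated nodes each count as one component
#' and the empty graph has zero.
#'
#' @param g an igraph.
#' @return non-negative integer component count.
#' @export
connectedComponentCount <- function(g) {
  if (vcount(g) == 0L) return(0L)
  components(g, mode = "weak")$no
}

#' k-shell (core) decomposition
#'
#' Standard iterative-pruning core index: \code{ks(i)} is the largest k such
#' that node i survives repeated removal of all nodes with degree < k.
#'
#' @param g an undirected igraph.
#' @return named integer vector of shell indices.
#' @export
kShell <- function(g) {
  if (is_directed(g))
    stop("k-shell decomposition is only supported for undirected graphs")
  ks <- coreness(g)
  names(ks) <- V(g)$name
  ks
}

# Replica label used across supra-graph computations.
.replicaName <- function(layer, node) paste(layer, node, sep = "::")

# Flatten a multilayer network into one igraph over (layer, node) replicas.
# Edge attributes: weight, and type = "intra" | "inter".
.supraGraph <- function(m) {
  ln <- layerNames(m)
  nodes <- unlist(lapply(ln, function(la)
    .replicaName(la, V(layers(m)[[la]])$name)), use.names = FALSE)
  src <- dst <- character(0)
  wts <- numeric(0)
  typ <- character(0)
  for (la in ln) {
    g <- layers(m)[[la]]
    if (ecount(g) == 0L) next
    el <- as_edgelist(g)
    w <- if ("weight" %in% edge_attr_names(g)) E(g)$weight else
      rep(1, ecount(g))
    src <- c(src, .replicaName(la, el[, 1]))
    dst <- c(dst, .replicaName(la, el[, 2]))
    wts <- c(wts, w)
    typ <- c(typ, rep("intra", nrow(el)))
  }
  ie <- interlayerEdges(m)
  if (nrow(ie) > 0L) {
    src <- c(src, .replicaName(ie$layer1, ie$node1))
    dst <- c(dst, .replicaName(ie$layer2, ie$node2))
    wts <- c(wts, ie$weight)
    typ <- c(typ, rep("inter", nrow(ie)))
  }
  sg <- make_empty_graph(n = length(nodes), directed = FALSE)
  V(sg)$name <- nodes
  V(sg)$layer <- rep(ln, vapply(layers(m), vcount, numeric(1)))
  V(sg)$node <- sub("^[^:]*::", "", nodes)
  if (length(src)) {
    sg <- add_edges(sg, rbind(match(src, nodes), match(dst, nodes)))
    E(sg)$weight <- wts
    E(sg)$type <- typ
  }
  sg
}

#' @rdname supraAdjacency
#' @export
setMethod("supraAdjacency", "MultilayerNetwork", function(x, ...) {
  sg <- .supraGraph(x)
  n <- vcount(sg)
  el <- as_edgelist(sg, names = FALSE)
  w <- if (ecount(sg)) E(sg)$weight else numeric(0)
  A <- sparseMatrix(i = c(el[, 1], el[, 2]), j = c(el[, 2], el[, 1]),
                    x = c(w, w), dims = c(n, n),
                    dimnames = list(V(sg)$name, V(sg)$name))
  A
})

.summaryFromGraph <- function(g, nLayers = NA_integer_,
                              nIntra = NA_integer_, nInter = NA_integer_) {
  if (vcount(g) == 0L) stop("cannot summarise an empty graph")
  k <- degree(g)
  flagged <- FALSE
  if (is_connected(g)) {
    dbar <- mean_distance(g, weights = NA)
  } else {
    comp <- components(g)
    big <- which.max(comp$csize)
    sub <- induced_subgraph(g, which(comp$membership == big))
    dbar <- if (vcount(sub) > 1L) mean_distance(sub, weights = NA) else
      NA_real_
    flagged <- TRUE
  }
  r <- suppressWarnings(assortativity_degree(g))
  if (!is.finite(r)) r <- NA_real_
  bc <- if (mean(k^2) > mean(k)) mean(k) / (mean(k^2) - mean(k)) else NA_real_
  new("NetworkSummary",
      nNodes = as.integer(vcount(g)), nEdges = as.integer(ecount(g)),
      nLayers = as.integer(nLayers), nIntraEdges = as.integer(nIntra),
      nInterEdges = as.integer(nInter),
      avgDegree = mean(k), avgPath = dbar,
      avgClustering = transitivity(g, type = "localaverage",
                                   isolates = "zero"),
      assortativity = r,
      heterogeneity = mean(k^2) / mean(k)^2,
      epidemicThreshold = bc,
      pathOnLargestComponent = flagged)
}

#' @rdname networkSummary
#' @export
setMethod("networkSummary", "igraph", function(x, ...) .summaryFromGraph(x))

#' @rdname networkSummary
#' @export
setMethod("networkSummary", "MultilayerNetwork", function(x, ...) {
  sg <- .supraGraph(x)
  .summaryFromGraph(sg, nLayers = nLayers(x),
                    nIntra = sum(vapply(layers(x), ecount, numeric(1))),
                    nInter = nrow(interlayerEdges(x)))
})
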