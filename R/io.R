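# Plain-text network I/O.
#
# Monolayer edge list:   src <TAB> dst [<TAB> weight]
# Multiplex intra file:  layer <TAB> src <TAB> dst [<TAB> weight]
# Multiplex inter file:  src <TAB> layerA <TAB> dst <TAB> layerB [<TAB> weight]
# Any run of whitespace separates fields; lines starting with '#' and blank
# lines are ignored. Missing weights default to 1; weights must be > 0.

.parseLines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  list(lineno = keep, fields = lapply(raw[keep], function(l)
    strsplit(trimws(l), "\\s+")[[1]]))
}

.parseWeight <- function(txt, lineno, path) {
  w <- suppressWarnings(as.numeric(txt))
  if (is.na(w))
    stop(sprintf("%s: line %d: weight '%s' is not a number", path, lineno, txt))
  if (w <= 0)
    stop(sprintf("%s: line %d: weight must be > 0 (got %s)", path, lineno, txt))
  w
}

.buildGraph <- function(nodes, src, dst, weight, directed) {
  g <- make_empty_graph(n = length(nodes), directed = directed)
  V(g)$name <- nodes
  if (length(src)) {
    g <- add_edges(g, rbind(match(src, nodes), match(dst, nodes)))
    E(g)$weight <- weight
  }
  g
}

#' Read a monolayer network from a whitespace-separated edge list
#'
#' Each non-comment line holds \code{src dst} or \code{src dst weight}. Nodes
#' are kept in order of first appearance; missing weights default to 1.
#' Self-loops and duplicate edges (per unordered pair when undirected, per
#' ordered pair when directed) are rejected.
#'
#' @param path path to the edge-list file.
#' @param directed logical; read edges as directed arcs (default FALSE).
#' @param weighted logical; when FALSE any third column is ignored and all
#'   weights are set to 1 (default TRUE: use weights when present).
#' @return an igraph with vertex names and an edge \code{weight} attribute.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B C 2.5"), f)
#' g <- readEdgeList(f)
#' igraph::ecount(g)
#' @export
readEdgeList <- function(path, directed = FALSE, weighted = TRUE) {
  p <- .parseLines(path)
  nodes <- character(0)
  src <- dst <- character(0)
  wts <- numeric(0)
  for (k in seq_along(p$fields)) {
    f <- p$fields[[k]]
    ln <- p$lineno[k]
    if (!(length(f) %in% c(2L, 3L)))
      stop(sprintf("%s: line %d: expected 2 or 3 fields, got %d",
                   path, ln, length(f)))
    w <- if (length(f) == 3L && weighted) .parseWeight(f[3], ln, path) else 1
    if (f[1] == f[2])
      stop(sprintf("%s: line %d: self-loop on node '%s'", path, ln, f[1]))
    for (nd in f[1:2]) if (!(nd %in% nodes)) nodes <- c(nodes, nd)
    src <- c(src, f[1]); dst <- c(dst, f[2]); wts <- c(wts, w)
  }
  key <- if (directed) paste(src, dst) else
    paste(pmin(src, dst), pmax(src, dst))
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate edge '%s'", path, key[duplicated(key)][1]))
  .buildGraph(nodes, src, dst, wts, directed)
}

#' Write a monolayer network as a whitespace-separated edge list
#'
#' Inverse of [readEdgeList()]: one \code{src dst weight} line per edge, in
#' the graph's edge order, so a read-write-read cycle preserves node order
#' and weights.
#'
#' @param g an igraph with vertex names.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(g, path) {
  el <- as_edgelist(g)
  w <- if ("weight" %in% edge_attr_names(g)) E(g)$weight else
    rep(1, ecount(g))
  writeLines(sprintf("%s\t%s\t%s", el[, 1], el[, 2],
                     vapply(w, function(x) format(x, digits = 15),
                            character(1))), path)
  invisible(path)
}

#' Read a multilayer network from multiplex edge-list files
#'
#' The intra-layer file holds \code{layer src dst [weight]} lines; layers are
#' ordered by first appearance and each becomes one undirected igraph. The
#' optional inter-layer file holds \code{src layerA dst layerB [weight]}
#' coupling lines between replicas of (possibly different) nodes in two
#' distinct layers.
#'
#' @param intraPath path to the intra-layer edge list.
#' @param interPath optional path to the inter-layer coupling list.
#' @param directed logical; read intra-layer edges as directed (default FALSE).
#' @return a [MultilayerNetwork-class].
#' @export
readMultiplex <- function(intraPath, interPath = NULL, directed = FALSE) {
  p <- .parseLines(intraPath)
  layer <- src <- dst <- character(0)
  wts <- numeric(0)
  for (k in seq_along(p$fields)) {
    f <- p$fields[[k]]
    ln <- p$lineno[k]
    if (!(length(f) %in% c(3L, 4L)))
      stop(sprintf("%s: line %d: expected 3 or 4 fields, got %d",
                   intraPath, ln, length(f)))
    w <- if (length(f) == 4L) .parseWeight(f[4], ln, intraPath) else 1
    if (f[2] == f[3])
      stop(sprintf("%s: line %d: self-loop on node '%s'", intraPath, ln, f[2]))
    layer <- c(layer, f[1]); src <- c(src, f[2]); dst <- c(dst, f[3])
    wts <- c(wts, w)
  }
  layerOrder <- unique(layer)
  graphs <- lapply(layerOrder, function(la) {
    i <- which(layer == la)
    nodes <- unique(as.vector(rbind(src[i], dst[i])))
    .buildGraph(nodes, src[i], dst[i], wts[i], directed)
  })
  names(graphs) <- layerOrder

  ie <- data.frame(node1 = character(0), layer1 = character(0),
                   node2 = character(0), layer2 = character(0),
                   weight = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(interPath)) {
    q <- .parseLines(interPath)
    for (k in seq_along(q$fields)) {
      f <- q$fields[[k]]
      ln <- q$lineno[k]
      if (!(length(f) %in% c(4L, 5L)))
        stop(sprintf("%s: line %d: expected 4 or 5 fields, got %d",
                     interPath, ln, length(f)))
      w <- if (length(f) == 5L) .parseWeight(f[5], ln, interPath) else 1
      if (f[2] == f[4])
        stop(sprintf("%s: line %d: inter-layer edge within one layer '%s'",
                     interPath, ln, f[2]))
      if (!(f[2] %in% layerOrder) || !(f[4] %in% layerOrder))
        stop(sprintf("%s: line %d: unknown layer label '%s'", interPath, ln,
                     setdiff(c(f[2], f[4]), layerOrder)[1]))
      ie <- rbind(ie, data.frame(node1 = f[1], layer1 = f[2], node2 = f[3],
                                 layer2 = f[4], weight = w,
                                 stringsAsFactors = FALSE))
    }
  }
  new("MultilayerNetwork", layers = graphs, interEdges = ie)
}

#' Write a multilayer network as multiplex edge-list files
#'
#' Inverse of [readMultiplex()].
#'
#' @param m a [MultilayerNetwork-class].
#' @param intraPath output path for the intra-layer edge list.
#' @param interPath optional output path for the inter-layer couplings
#'   (required when \code{m} has any).
#' @return invisibly, \code{intraPath}.
#' @export
writeMultiplex <- function(m, intraPath, interPath = NULL) {
  lines <- character(0)
  for (la in layerNames(m)) {
    g <- layers(m)[[la]]
    if (ecount(g) == 0L) next
    el <- as_edgelist(g)
    w <- if ("weight" %in% edge_attr_names(g)) E(g)$weight else
      rep(1, ecount(g))
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s", la, el[, 1], el[, 2],
                              vapply(w, function(x) format(x, digits = 15),
                                     character(1))))
  }
  writeLines(lines, intraPath)
  ie <- interlayerEdges(m)
  if (nrow(ie) > 0L) {
    if (is.null(interPath))
      stop("network has inter-layer edges but no interPath was given")
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s", ie$node1, ie$layer1, ie$node2,
                       ie$layer2,
                       vapply(ie$weight, function(x) format(x, digits = 15),
                              character(1))), interPath)
  } else if (!is.null(interPath)) {
    writeLines(character(0), interPath)
  }
  invisible(intraPath)
}
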