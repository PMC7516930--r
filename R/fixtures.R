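# Built-in worked-example networks and seeded synthetic generators.

#' Krackhardt's kite network
#'
#' The canonical 10-node, 18-edge kite: a dense clique-like body
#' (Andre, Beverley, Carol, Diane, Ed, Fernando, Garth) attached to a tail
#' Heather - Ike - Jane. Diane has the highest degree (6) but the tail gives
#' Heather the highest betweenness and Fernando/Garth the highest closeness —
#' the standard illustration that different centralities crown different
#' nodes. Degree sequence: 4, 4, 3, 6, 3, 5, 5, 3, 2, 1.
#'
#' @return an undirected igraph with named vertices.
#' @examples
#' g <- kiteNetwork()
#' igraph::degree(g)["Diane"]   # 6
#' @export
kiteNetwork <- function() {
  edges <- c(
    "Andre", "Beverley", "Andre", "Carol", "Andre", "Diane",
    "Andre", "Fernando",
    "Beverley", "Diane", "Beverley", "Ed", "Beverley", "Garth",
    "Carol", "Diane", "Carol", "Fernando",
    "Diane", "Ed", "Diane", "Fernando", "Diane", "Garth",
    "Ed", "Garth",
    "Fernando", "Garth", "Fernando", "Heather",
    "Garth", "Heather",
    "Heather", "Ike",
    "Ike", "Jane")
  nodes <- c("Andre", "Beverley", "Carol", "Diane", "Ed", "Fernando",
             "Garth", "Heather", "Ike", "Jane")
  m <- matrix(edges, ncol = 2, byrow = TRUE)
  g <- make_empty_graph(n = 10, directed = FALSE)
  V(g)$name <- nodes
  g <- add_edges(g, rbind(match(m[, 1], nodes), match(m[, 2], nodes)))
  E(g)$weight <- rep(1, 18)
  g
}

#' Seeded random monolayer network
#'
#' Standard generators with deterministic labels \code{v1..vn}:
#' Erdős–Rényi \code{G(n, p)} (\code{"er"}), Barabási–Albert preferential
#' attachment with m edges per new node (\code{"ba"}), and Watts–Strogatz
#' with neighbourhood half-width k/2 and rewiring probability p
#' (\code{"ws"}).
#'
#' @param model one of \code{"er"}, \code{"ba"}, \code{"ws"}.
#' @param n number of nodes.
#' @param p edge probability (er) or rewiring probability (ws).
#' @param m edges added per step (ba, default 2).
#' @param k even ring-lattice degree (ws, default 4).
#' @param seed integer RNG seed; identical arguments give identical graphs.
#' @return an undirected igraph with named vertices.
#' @export
randomGraph <- function(model = c("er", "ba", "ws"), n, p = 0.1, m = 2L,
                        k = 4L, seed = 1L) {
  model <- match.arg(model)
  if (n < 1) stop("n must be positive")
  set.seed(seed)
  g <- switch(model,
    er = {
      if (p < 0 || p > 1) stop("p must lie in [0, 1]")
      sample_gnp(n, p)
    },
    ba = {
      if (m < 1 || m >= n) stop("m must satisfy 1 <= m < n")
      sample_pa(n, m = m, directed = FALSE)
    },
    ws = {
      if (k %% 2 != 0 || k < 2) stop("k must be a positive even integer")
      if (p < 0 || p > 1) stop("p must lie in [0, 1]")
      sample_smallworld(1, n, k / 2, p)
    })
  V(g)$name <- paste0("v", seq_len(n))
  g
}

#' Seeded random multilayer network
#'
#' L Erdős–Rényi layers over the same node labels \code{v1..vn}; each node is
#' coupled to its own replica in every other layer independently with
#' probability \code{pInter} (unit coupling weights).
#'
#' @param L number of layers.
#' @param n nodes per layer.
#' @param pIntra intra-layer edge probability.
#' @param pInter replica coupling probability per layer pair.
#' @param seed integer RNG seed.
#' @return a [MultilayerNetwork-class] with layers \code{L1..LL}.
#' @export
toyMultilayer <- function(L = 2L, n = 10L, pIntra = 0.3, pInter = 0.5,
                          seed = 1L) {
  if (L < 1) stop("L must be at least 1")
  if (pIntra < 0 || pIntra > 1 || pInter < 0 || pInter > 1)
    stop("probabilities must lie in [0, 1]")
  set.seed(seed)
  lays <- lapply(seq_len(L), function(a) {
    g <- sample_gnp(n, pIntra)
    V(g)$name <- paste0("v", seq_len(n))
    if (ecount(g)) E(g)$weight <- rep(1, ecount(g))
    g
  })
  names(lays) <- paste0("L", seq_len(L))
  ie <- data.frame(node1 = character(0), layer1 = character(0),
                   node2 = character(0), layer2 = character(0),
                   weight = numeric(0), stringsAsFactors = FALSE)
  if (L > 1) {
    for (a in seq_len(L - 1)) for (b in seq(a + 1, L)) {
      keep <- runif(n) < pInter
      if (any(keep))
        ie <- rbind(ie, data.frame(
          node1 = paste0("v", which(keep)), layer1 = paste0("L", a),
          node2 = paste0("v", which(keep)), layer2 = paste0("L", b),
          weight = 1, stringsAsFactors = FALSE))
    }
  }
  new("MultilayerNetwork", layers = lays, interEdges = ie)
}

#' Zachary karate club network
#'
#' The classic 34-node, 78-edge friendship network of a university karate
#' club, used as a benchmark for summary statistics and thresholds.
#'
#' @return an undirected igraph with vertices named \code{v1..v34}.
#' @export
karateClub <- function() {
  g <- make_graph("Zachary")
  V(g)$name <- paste0("v", seq_len(vcount(g)))
  g
}
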