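# Comparison centralities. Unless noted, scores are computed on the
# unit-weight skeleton (a_ij in {0,1}): no weighted variant of these
# indicators is defined here, edge weights only affect spreading and the INF
# indicator. Normalization conventions: degree by 1/(N-1), betweenness by
# 2/((N-1)(N-2)), closeness as (N-1)/sum(d), eigenvector and Katz by the
# L2 norm.

.scoreTable <- function(method, params, values, nodeNames) {
  new("ScoreTable", method = method, params = params,
      scores = setNames(as.numeric(values), nodeNames))
}

.unitAdjacency <- function(g) {
  as.matrix(as_adjacency_matrix(g, sparse = TRUE) > 0) * 1
}

#' Degree centrality
#'
#' Raw mode sums edge weights incident to each node (weighted degree);
#' normalized mode uses the unit-weight degree divided by N-1.
#'
#' @param g an igraph.
#' @param normalized logical (default TRUE).
#' @return a [ScoreTable-class].
#' @export
degreeCentrality <- function(g, normalized = TRUE) {
  if (normalized && vcount(g) < 2L)
    stop("normalized degree centrality needs at least 2 nodes")
  v <- if (normalized) degree(g) / (vcount(g) - 1) else strength(g)
  .scoreTable("dc", list(normalized = normalized), v, V(g)$name)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths between all node pairs passing through each
#' node (endpoints excluded), on hop distances. Normalized mode divides by
#' (N-1)(N-2)/2 for undirected graphs ((N-1)(N-2) for directed).
#'
#' @param g an igraph.
#' @param normalized logical (default TRUE).
#' @return a [ScoreTable-class].
#' @export
betweennessCentrality <- function(g, normalized = TRUE) {
  v <- betweenness(g, weights = NA, normalized = normalized)
  .scoreTable("bc", list(normalized = normalized), v, V(g)$name)
}

#' Closeness centrality
#'
#' \eqn{CC(i) = (N-1)/\sum_j d_{ij}} on hop distances for a connected graph.
#' On a disconnected graph each node is scored within its own component using
#' that component's size; singleton components score 0 (with a warning).
#'
#' @param g an igraph.
#' @return a [ScoreTable-class].
#' @export
closenessCentrality <- function(g) {
  comp <- components(g, mode = "weak")
  v <- numeric(vcount(g))
  if (any(comp$csize == 1L))
    warning("singleton component(s): closeness set to 0 for isolated nodes")
  for (c in seq_len(comp$no)) {
    idx <- which(comp$membership == c)
    if (length(idx) == 1L) { v[idx] <- 0; next }
    d <- distances(g, v = idx, to = idx, weights = NA)
    v[idx] <- (length(idx) - 1) / rowSums(d)
  }
  .scoreTable("cc", list(), v, V(g)$name)
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the unit-weight adjacency matrix, computed by
#' power iteration and L2-normalized so that all entries are non-negative and
#' the returned vector has unit Euclidean norm.
#'
#' @param g a connected undirected igraph.
#' @param tol convergence tolerance on the relative residual
#'   \eqn{\|Ax - \lambda x\| \le tol\,\|x\|} (default 1e-10).
#' @param maxIter maximum power iterations (default 10000).
#' @return a [ScoreTable-class].
#' @export
eigenvectorCentrality <- function(g, tol = 1e-10, maxIter = 10000L) {
  if (is_directed(g))
    stop("eigenvector centrality is only supported for undirected graphs")
  if (!is_connected(g))
    warning("graph is disconnected: the principal eigenvector concentrates ",
            "on one component")
  A <- .unitAdjacency(g)
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  lam <- 0
  for (it in seq_len(maxIter)) {
    y <- as.numeric(A %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) stop("adjacency matrix annihilates the start vector")
    y <- y / ny
    lam <- as.numeric(crossprod(y, A %*% y))
    if (sqrt(sum((as.numeric(A %*% y) - lam * y)^2)) <= tol * lam) {
      return(.scoreTable("ec", list(tol = tol, iterations = it),
                         abs(y), V(g)$name))
    }
    x <- y
  }
  stop(sprintf("eigenvector centrality did not converge in %d iterations",
               maxIter))
}

#' PageRank
#'
#' Fixed point of \eqn{PR(i) = (1-d)/N + d \sum_j a_{ji} PR(j)/k_j^{out}}.
#' The default damping 1.0 gives the pure adjacency recursion; 0.85 is the
#' conventional teleporting option. Undirected edges act as two arcs;
#' dangling nodes redistribute their mass uniformly; scores sum to 1.
#'
#' @param g an igraph.
#' @param damping damping factor in (0, 1] (default 1.0).
#' @param tol L1 convergence tolerance (default 1e-12).
#' @param maxIter maximum iterations (default 10000).
#' @return a [ScoreTable-class].
#' @export
pagerank <- function(g, damping = 1.0, tol = 1e-12, maxIter = 10000L) {
  if (damping <= 0 || damping > 1)
    stop("damping must lie in (0, 1]")
  n <- vcount(g)
  A <- if (is_directed(g)) {
    t(.unitAdjacency(g))   # column j holds arcs j -> i
  } else .unitAdjacency(g)
  kout <- colSums(A)
  dangling <- kout == 0
  Minv <- ifelse(dangling, 0, 1 / pmax(kout, 1))
  x <- rep(1 / n, n)
  for (it in seq_len(maxIter)) {
    spread <- as.numeric(A %*% (x * Minv)) + sum(x[dangling]) / n
    y <- (1 - damping) / n + damping * spread
    y <- (x + y) / 2       # lazy update: keeps d = 1 convergent on
    y <- y / sum(y)        # periodic (e.g. bipartite) structures
    if (sum(abs(y - x)) <= tol)
      return(.scoreTable("pr", list(damping = damping, iterations = it),
                         y, V(g)$name))
    x <- y
  }
  stop(sprintf("pagerank did not converge in %d iterations", maxIter))
}

#' Katz centrality
#'
#' Solves \eqn{x = \alpha A x + \beta \mathbf{1}} on the unit-weight
#' adjacency and L2-normalizes the solution. Requires
#' \eqn{\alpha < 1/\lambda_{max}}.
#'
#' @param g an igraph.
#' @param alpha attenuation factor (default 0.1).
#' @param beta baseline score (default 1.0).
#' @return a [ScoreTable-class].
#' @export
katzCentrality <- function(g, alpha = 0.1, beta = 1.0) {
  A <- .unitAdjacency(g)
  n <- nrow(A)
  lamMax <- if (n > 0 && any(A > 0)) max(abs(eigen(A, only.values = TRUE)$values))
            else 0
  if (lamMax > 0 && alpha >= 1 / lamMax)
    stop(sprintf("alpha = %g >= 1/lambda_max = %g: Katz series diverges",
                 alpha, 1 / lamMax))
  x <- solve(diag(n) - alpha * A, rep(beta, n))
  x <- x / sqrt(sum(x^2))
  .scoreTable("katz", list(alpha = alpha, beta = beta), x, V(g)$name)
}

#' Local clustering coefficient
#'
#' \eqn{C_i} = closed triangles through i over wedges at i, on the
#' unit-weight skeleton; nodes of degree < 2 score 0.
#'
#' @param g an undirected igraph.
#' @return a [ScoreTable-class].
#' @export
clusteringCoefficient <- function(g) {
  v <- transitivity(g, type = "local", isolates = "zero")
  .scoreTable("cluster", list(), v, V(g)$name)
}

# shared distance-truncated gravity sum:
#   sum over 0 < d_ij <= R of mass_i * mass_j / d_ij^2
.gravitySum <- function(g, mass, R) {
  d <- distances(g, weights = NA)
  vapply(seq_len(vcount(g)), function(i) {
    j <- which(d[i, ] > 0 & d[i, ] <= R & is.finite(d[i, ]))
    sum(mass[i] * mass[j] / d[i, j]^2)
  }, numeric(1))
}

#' Gravity centrality
#'
#' \eqn{G(i) = \sum_{j \in \psi_i} ks(i)\,ks(j)/d_{ij}^2} where
#' \eqn{\psi_i} holds the nodes within 3 hops of i and ks is the k-shell
#' index.
#'
#' @param g an undirected igraph.
#' @return a [ScoreTable-class].
#' @export
gravityCentrality <- function(g) {
  if (is_directed(g))
    stop("gravity centrality is only supported for undirected graphs")
  v <- .gravitySum(g, as.numeric(kShell(g)), 3L)
  .scoreTable("gr", list(radius = 3L), v, V(g)$name)
}

#' Gravity-plus centrality
#'
#' \eqn{G^+(i) = \sum_{j \in \Gamma_i} G(j)}: the gravity scores of the
#' direct neighbours, summed.
#'
#' @param g an undirected igraph.
#' @return a [ScoreTable-class].
#' @export
gravityPlus <- function(g) {
  gs <- scores(gravityCentrality(g))
  v <- vapply(V(g)$name, function(nm)
    sum(gs[names(neighbors(g, nm))]), numeric(1))
  .scoreTable("grplus", list(radius = 3L), v, V(g)$name)
}

#' Local-gravity centrality
#'
#' \eqn{LGR(i) = \sum_{0 < d_{ij} \le R} k_i k_j / d_{ij}^2} with plain
#' degrees in place of k-shell indices. \code{R = "auto"} uses half the
#' diameter of the largest component, rounded up.
#'
#' @param g an igraph.
#' @param R positive integer truncation radius, or \code{"auto"}.
#' @return a [ScoreTable-class].
#' @export
localGravity <- function(g, R = "auto") {
  if (identical(R, "auto")) {
    comp <- components(g, mode = "weak")
    sub <- induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    R <- max(1L, as.integer(ceiling(diameter(sub, weights = NA) / 2)))
  }
  if (!is.numeric(R) || R < 1) stop("R must be a positive integer or 'auto'")
  v <- .gravitySum(g, as.numeric(degree(g)), R)
  .scoreTable("lgr", list(R = as.integer(R)), v, V(g)$name)
}
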