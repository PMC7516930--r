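# Discrete-time SIR spreading. Synchronous (generation-based) updates: at
# each step every currently infectious node attempts each of its susceptible
# neighbours independently with per-contact probability min(1, w_ij * beta),
# and recovers with probability gamma after its attempts for that step. Nodes
# infected during a step become infectious at the next step. With gamma = 1
# every node transmits during exactly one step. Iterations are the number of
# synchronous steps until the infectious set is empty, counting the step of
# the last recovery.

# Precompute adjacency lists and per-contact transmission probabilities.
.sirPrep <- function(g, beta) {
  n <- vcount(g)
  w <- if ("weight" %in% edge_attr_names(g)) E(g)$weight else
    rep(1, ecount(g))
  el <- as_edgelist(g, names = FALSE)
  nbr <- vector("list", n)
  prb <- vector("list", n)
  for (i in seq_len(n)) { nbr[[i]] <- integer(0); prb[[i]] <- numeric(0) }
  p <- pmin(1, w * beta)
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      a <- el[e, 1]; b <- el[e, 2]
      nbr[[a]] <- c(nbr[[a]], b); prb[[a]] <- c(prb[[a]], p[e])
      if (!is_directed(g)) {
        nbr[[b]] <- c(nbr[[b]], a); prb[[b]] <- c(prb[[b]], p[e])
      }
    }
  }
  list(nbr = nbr, prb = prb, n = n)
}

.sirOnce <- function(prep, seedIds, gamma) {
  states <- integer(prep$n)          # 0 = S, 1 = I, 2 = R
  infected <- sort(seedIds)
  states[infected] <- 1L
  steps <- 0L
  while (length(infected)) {
    steps <- steps + 1L
    newInf <- integer(0)
    for (v in infected) {
      nb <- prep$nbr[[v]]
      if (!length(nb)) next
      sus <- which(states[nb] == 0L)
      if (!length(sus)) next
      hit <- sus[runif(length(sus)) < prep$prb[[v]][sus]]
      if (length(hit)) {
        ids <- nb[hit]
        states[ids] <- 1L
        newInf <- c(newInf, ids)
      }
    }
    rec <- runif(length(infected)) < gamma
    states[infected[rec]] <- 2L
    infected <- sort(c(infected[!rec], newInf))
  }
  list(recovered = which(states == 2L), steps = steps)
}

.checkSIRParams <- function(beta, gamma) {
  if (!is.numeric(beta) || beta < 0 || beta > 1)
    stop("beta must lie in [0, 1]")
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]")
}

#' Single SIR spreading run on a monolayer network
#'
#' Runs one synchronous discrete-time SIR epidemic from the given seed set
#' using the current RNG state (call \code{set.seed()} beforehand for a
#' reproducible run). Weighted edges transmit with probability
#' \code{min(1, w * beta)}.
#'
#' @param g an igraph.
#' @param seeds non-empty character vector of seed node names.
#' @param beta per-contact infection probability in [0, 1].
#' @param gamma per-step recovery probability in (0, 1] (default 1).
#' @return list with \code{recovered} (character vector of finally recovered
#'   nodes, always including the seeds) and \code{steps}.
#' @export
sirRun <- function(g, seeds, beta, gamma = 1) {
  .checkSIRParams(beta, gamma)
  ids <- match(seeds, V(g)$name)
  if (length(ids) == 0L || anyNA(ids))
    stop("seeds must be a non-empty subset of the graph's nodes")
  out <- .sirOnce(.sirPrep(g, beta), ids, gamma)
  list(recovered = V(g)$name[out$recovered], steps = out$steps)
}

#' Single SIR spreading run on a multilayer network
#'
#' Identical dynamics on the supra-graph: intra-layer contacts transmit with
#' probability \code{min(1, w * beta)} and inter-layer contacts with
#' \code{min(1, w_ij * beta)} (the coupling weight scales beta).
#'
#' @param m a [MultilayerNetwork-class].
#' @param seeds non-empty character vector of replica names
#'   (\code{"layer::node"}).
#' @param beta per-contact infection probability in [0, 1].
#' @param gamma per-step recovery probability in (0, 1] (default 1).
#' @param countPhysical when TRUE, \code{recovered} lists distinct physical
#'   nodes instead of replicas.
#' @return list with \code{recovered} and \code{steps} as in [sirRun()].
#' @export
sirRunMultilayer <- function(m, seeds, beta, gamma = 1,
                             countPhysical = FALSE) {
  sg <- .supraGraph(m)
  out <- sirRun(sg, seeds, beta, gamma)
  if (countPhysical)
    out$recovered <- unique(sub("^[^:]*::", "", out$recovered))
  out
}

#' Repeated-run SIR spreading influence of a seed set
#'
#' Aggregates \code{nRuns} independent SIR runs from the same seed(s),
#' reporting per-run and mean final recovered counts, mean steps, and the
#' spreading influence \eqn{P(i) = N_R / N}. Works on a monolayer graph
#' (seed node names) or a multilayer network (replica names; dynamics on the
#' supra-graph).
#'
#' @param g an igraph or [MultilayerNetwork-class].
#' @param seeds character vector of seed node (or replica) names.
#' @param beta per-contact infection probability (default 0.35).
#' @param gamma per-step recovery probability (default 1).
#' @param nRuns number of independent runs (default 10000).
#' @param rngSeed optional integer; when given, \code{set.seed(rngSeed)} is
#'   called first so the whole estimate replays bit-identically.
#' @param countPhysical multilayer only: count distinct physical nodes
#'   rather than replicas.
#' @return a [SIROutcome-class].
#' @examples
#' \donttest{
#' out <- spreadEstimate(kiteNetwork(), "Diane", beta = 0.35, nRuns = 2000,
#'                       rngSeed = 1)
#' meanRecovered(out)   # about 5.32
#' }
#' @export
spreadEstimate <- function(g, seeds, beta = 0.35, gamma = 1,
                           nRuns = 10000L, rngSeed = NULL,
                           countPhysical = FALSE) {
  .checkSIRParams(beta, gamma)
  if (nRuns < 1) stop("nRuns must be at least 1")
  if (!is.null(rngSeed)) set.seed(rngSeed)
  if (is(g, "MultilayerNetwork")) g <- .supraGraph(g)
  ids <- match(seeds, V(g)$name)
  if (length(ids) == 0L || anyNA(ids))
    stop("seeds must be a non-empty subset of the graph's nodes")
  prep <- .sirPrep(g, beta)
  rec <- integer(nRuns)
  its <- integer(nRuns)
  phys <- V(g)$name
  if (countPhysical) phys <- sub("^[^:]*::", "", phys)
  for (r in seq_len(nRuns)) {
    out <- .sirOnce(prep, ids, gamma)
    rec[r] <- if (countPhysical) length(unique(phys[out$recovered])) else
      length(out$recovered)
    its[r] <- out$steps
  }
  nTot <- if (countPhysical) length(unique(phys)) else prep$n
  new("SIROutcome", recovered = rec, iterations = its,
      nNodes = as.integer(nTot),
      config = list(beta = beta, gamma = gamma, nRuns = as.integer(nRuns),
                    seeds = seeds, rngSeed = rngSeed,
                    countPhysical = countPhysical))
}

#' SIR epidemic threshold of a network
#'
#' The degree-based estimate
#' \eqn{\beta_c \approx \langle k\rangle / (\langle k^2\rangle - \langle k\rangle)}
#' from the unit-weight degree sequence.
#'
#' @param g an igraph.
#' @return the threshold, a positive number.
#' @examples
#' epidemicThreshold(kiteNetwork())   # 0.3158
#' @export
epidemicThreshold <- function(g) {
  k <- degree(g)
  if (mean(k^2) <= mean(k))
    stop("epidemic threshold undefined: <k^2> <= <k>")
  mean(k) / (mean(k^2) - mean(k))
}
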