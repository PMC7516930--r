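test_that("degree centrality handles raw weights and normalization", {
  g <- kiteNetwork()
  expect_equal(unname(scores(degreeCentrality(g))["Diane"]), 6 / 9)
  igraph::E(g)$weight <- rep(2, igraph::ecount(g))
  expect_equal(unname(scores(degreeCentrality(g, normalized = FALSE))["Diane"]),
               12)
  single <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(single)$name <- "a"
  expect_error(degreeCentrality(single), "at least 2 nodes")
  g2 <- namedGraph(c("a", "b"), nodes = c("a", "b", "iso"))
  expect_equal(unname(scores(degreeCentrality(g2))["iso"]), 0)
})

test_that("betweenness matches hand values and a brute-force path oracle", {
  p3 <- pathGraph(c("a", "b", "c"))
  expect_equal(unname(scores(betweennessCentrality(p3, normalized = FALSE))),
               c(0, 1, 0))

  # brute-force all-pairs shortest-path enumeration on small random graphs
  for (seed in c(3, 8)) {
    g <- randomGraph("er", 8, p = 0.45, seed = seed)
    raw <- scores(betweennessCentrality(g, normalized = FALSE))
    d <- igraph::distances(g, weights = NA)
    oracle <- setNames(numeric(8), igraph::V(g)$name)
    nodes <- igraph::V(g)$name
    for (s in 1:7) for (t in (s + 1):8) {
      if (!is.finite(d[s, t])) next
      paths <- igraph::all_shortest_paths(g, from = s, to = t)$res
      interior <- unlist(lapply(paths, function(p) setdiff(names(p),
                                                           nodes[c(s, t)])))
      if (length(interior)) {
        tb <- table(interior) / length(paths)
        oracle[names(tb)] <- oracle[names(tb)] + as.numeric(tb)
      }
    }
    expect_equal(raw, oracle, tolerance = 1e-10)
  }
})

test_that("closeness uses component-wise scoring on disconnected input", {
  expect_equal(unname(scores(closenessCentrality(completeGraph(4)))),
               rep(1, 4))
  # two components: each scored within its own component
  g <- namedGraph(c("a", "b", "b", "c", "x", "y"))
  cc <- scores(closenessCentrality(g))
  expect_equal(unname(cc["b"]), 1)        # (3-1)/2
  expect_equal(unname(cc["a"]), 2 / 3)
  expect_equal(unname(cc["x"]), 1)        # (2-1)/1
  g2 <- namedGraph(c("a", "b"), nodes = c("a", "b", "iso"))
  expect_warning(cc2 <- scores(closenessCentrality(g2)), "singleton")
  expect_equal(unname(cc2["iso"]), 0)
})

test_that("eigenvector centrality satisfies the eigen-residual bound", {
  g <- kiteNetwork()
  st <- eigenvectorCentrality(g, tol = 1e-12)
  x <- scores(st)
  expect_equal(sqrt(sum(x^2)), 1, tolerance = 1e-10)
  A <- (as.matrix(igraph::as_adjacency_matrix(g)) > 0) * 1
  lam <- as.numeric(crossprod(x, A %*% x))
  expect_lt(sqrt(sum((A %*% x - lam * x)^2)), 1e-8)
  expect_true(all(x >= 0))
  expect_equal(unname(scores(eigenvectorCentrality(completeGraph(4)))),
               rep(0.5, 4), tolerance = 1e-8)
  expect_error(eigenvectorCentrality(kiteNetwork(), maxIter = 2L),
               "did not converge")
  # independent cross-check against igraph's implementation (rescaled to L2)
  ig <- igraph::eigen_centrality(g)$vector
  expect_equal(unname(x), unname(ig / sqrt(sum(ig^2))), tolerance = 1e-6)
})

test_that("pagerank normalizes to 1 and solves symmetric/cyclic cases", {
  g <- kiteNetwork()
  expect_equal(sum(scores(pagerank(g))), 1, tolerance = 1e-10)
  expect_equal(unname(scores(pagerank(completeGraph(5), damping = 1))),
               rep(0.2, 5), tolerance = 1e-8)
  cyc <- namedGraph(c("a", "b", "b", "c", "c", "a"), directed = TRUE)
  expect_equal(unname(scores(pagerank(cyc, damping = 1))), rep(1 / 3, 3),
               tolerance = 1e-8)
  expect_error(pagerank(g, damping = 0), "damping")
})

test_that("Katz centrality solves the resolvent system and detects divergence", {
  edgeless <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(edgeless)$name <- letters[1:4]
  expect_equal(unname(scores(katzCentrality(edgeless))), rep(0.5, 4))
  p3 <- pathGraph(c("a", "b", "c"))
  x <- scores(katzCentrality(p3))
  expect_gt(x["b"], x["a"])
  expect_equal(unname(x["a"]), unname(x["c"]))
  expect_error(katzCentrality(completeGraph(4), alpha = 0.5), "diverges")
})

test_that("clustering coefficient counts triangles over wedges", {
  expect_equal(unname(scores(clusteringCoefficient(completeGraph(3)))),
               rep(1, 3))
  expect_equal(unname(scores(clusteringCoefficient(starGraph(5)))),
               rep(0, 5))
  # brute-force triangle enumeration oracle on the kite
  g <- kiteNetwork()
  A <- (as.matrix(igraph::as_adjacency_matrix(g)) > 0) * 1
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  oracle <- ifelse(k < 2, 0, tri / choose(k, 2))
  expect_equal(unname(scores(clusteringCoefficient(g))), unname(oracle))
})

test_that("gravity family matches closed forms and hand evaluations", {
  expect_equal(unname(scores(gravityCentrality(completeGraph(3)))),
               rep(8, 3))
  g <- kiteNetwork()
  gr <- scores(gravityCentrality(g))
  # Jane: ks 1; Ike d1 ks1, Heather d2 ks2, Fernando/Garth d3 ks3
  expect_equal(unname(gr["Jane"]), 1 * (1 / 1 + 2 / 4 + 3 / 9 + 3 / 9),
               tolerance = 1e-12)
  gp <- scores(gravityPlus(g))
  for (v in igraph::V(g)$name) {
    expect_equal(unname(gp[v]),
                 sum(gr[names(igraph::neighbors(g, v))]), tolerance = 1e-12)
  }
})

test_that("local gravity matches degree products and grows with R", {
  g <- kiteNetwork()
  l1 <- scores(localGravity(g, R = 1))
  expect_equal(unname(l1["Jane"]), 1 * 2)
  expect_equal(unname(l1["Diane"]), 6 * (4 + 4 + 3 + 3 + 5 + 5))
  s6 <- starGraph(6)
  ls <- scores(localGravity(s6, R = 1))
  expect_equal(unname(ls["hub"]), 25)
  expect_equal(unname(ls["s1"]), 5)
  # monotone non-decreasing in R
  prev <- l1
  for (R in 2:4) {
    cur <- scores(localGravity(g, R = R))
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
  # auto radius = ceil(diameter / 2)
  expect_equal(methodParams(localGravity(g))$R, 2L)
})

test_that("score tables are permutation-equivariant", {
  g <- randomGraph("er", 12, p = 0.3, seed = 21)
  perm <- sample(12)
  gp <- igraph::permute(g, perm)
  for (fn in list(degreeCentrality, betweennessCentrality,
                  closenessCentrality, clusteringCoefficient,
                  function(x) localGravity(x, R = 2), infScores)) {
    a <- scores(fn(g)); b <- scores(fn(gp))
    expect_equal(b[names(a)], a, tolerance = 1e-10)
  }
})
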