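test_that("INF at R = 1 equals the one-line neighbourhood oracle", {
  # 100 seeded random graphs, three families, with and without weights
  for (i in 1:100) {
    model <- c("er", "ba", "ws")[(i %% 3) + 1]
    g <- randomGraph(model, n = 8 + (i %% 17), p = 0.25, m = 2, k = 4,
                     seed = 1000 + i)
    if (i %% 4 == 0 && igraph::ecount(g) > 0) {
      set.seed(i)
      igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 3)
    }
    got <- suppressMessages(scores(infScores(g)))
    expect_equal(got, bruteINF(g), tolerance = 1e-12)
  }
})

test_that("logistic INF lies in (0,1), preserves the raw ranking, and handles isolates", {
  g <- randomGraph("er", 30, p = 0.15, seed = 77)
  logi <- suppressMessages(scores(infScores(g, normalization = "logistic")))
  raw <- suppressMessages(scores(infScores(g, normalization = "raw")))
  expect_true(all(logi > 0 & logi < 1))
  expect_true(all(logi[igraph::degree(g) >= 1] > 0.5))
  expect_equal(order(logi), order(raw))
  iso <- namedGraph(c("a", "b"), nodes = c("a", "b", "lone"))
  expect_message(st <- infScores(iso), "isolated")
  expect_equal(unname(scores(st)["lone"]), 0.5)
})

test_that("a pendant neighbour adds exactly 1 to the raw INF sum", {
  g <- kiteNetwork()
  before <- scores(infScores(g, normalization = "raw"))
  g2 <- igraph::add_vertices(g, 1, name = "pendant")
  g2 <- igraph::add_edges(g2, c(igraph::vcount(g2), match("Diane",
                                                          igraph::V(g2)$name)))
  igraph::E(g2)$weight[igraph::ecount(g2)] <- 1
  after <- scores(infScores(g2, normalization = "raw"))
  expect_equal(unname(after["Diane"] - before["Diane"]), 1)
})

test_that("doubling edge weights strictly increases raw INF of connected nodes", {
  g <- randomGraph("er", 15, p = 0.3, seed = 12)
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 2)
  a <- scores(infScores(g, normalization = "raw"))
  igraph::E(g)$weight <- igraph::E(g)$weight * 2
  b <- scores(infScores(g, normalization = "raw"))
  conn <- igraph::degree(g) > 0
  expect_true(all(b[conn] > a[conn]))
})

test_that("structurally equivalent kite nodes tie in every indicator", {
  g <- kiteNetwork()
  pairs <- list(c("Andre", "Beverley"), c("Carol", "Ed"),
                c("Fernando", "Garth"))
  for (fn in list(degreeCentrality, betweennessCentrality,
                  closenessCentrality, eigenvectorCentrality, pagerank,
                  katzCentrality, clusteringCoefficient, gravityCentrality,
                  gravityPlus, localGravity, infScores)) {
    s <- scores(fn(g))
    for (p in pairs) expect_equal(unname(s[p[1]]), unname(s[p[2]]),
                                  tolerance = 1e-9)
  }
})

test_that("multilayer INF reduces to monolayer for one uncoupled layer", {
  m <- toyMultilayer(L = 1, n = 12, pIntra = 0.3, pInter = 0, seed = 6)
  mono <- suppressMessages(scores(infScores(layers(m)[[1]])))
  multi <- suppressMessages(scores(infScoresMultilayer(m)))
  names(multi) <- sub("^L1::", "", names(multi))
  expect_equal(multi[names(mono)], mono, tolerance = 1e-12)
})

test_that("multilayer INF equals the supra-graph neighbourhood oracle", {
  # 2-layer toy: layer1 path a-b-c, layer2 edge a-c, inter edge (b,1)-(a,2)
  f <- withr::local_tempfile(); fi <- withr::local_tempfile()
  writeLines(c("1 a b", "1 b c", "2 a c"), f)
  writeLines("b 1 a 2", fi)
  m <- readMultiplex(f, fi)
  got <- scores(infScoresMultilayer(m))
  # supra degrees: (a,1)=1 (b,1)=3 (c,1)=1 (a,2)=2 (c,2)=1
  rawB1 <- 1 / 1 + 1 / 1 + 1 / 2    # a1, c1 intra + a2 inter
  expect_equal(unname(got["1::b"]), 1 / (1 + exp(-rawB1)), tolerance = 1e-12)
  # full oracle over the supra-adjacency
  A <- as.matrix(supraAdjacency(m))
  k <- colSums(A > 0)
  raw <- as.numeric((A > 0) %*% (1 / k))
  expect_equal(unname(got[rownames(A)]), 1 / (1 + exp(-raw)),
               tolerance = 1e-12)
})

test_that("identical uncoupled layers give each replica its per-layer score", {
  f <- withr::local_tempfile()
  writeLines(c("1 a b", "1 b c", "2 a b", "2 b c"), f)
  m <- readMultiplex(f)
  got <- scores(infScoresMultilayer(m))
  mono <- scores(infScores(pathGraph(c("a", "b", "c"))))
  expect_equal(unname(got[c("1::a", "1::b", "1::c")]), unname(mono))
  expect_equal(unname(got[c("2::a", "2::b", "2::c")]), unname(mono))
})

test_that("aggregated multilayer INF sums raw replica scores per physical node", {
  m <- toyMultilayer(L = 2, n = 6, pIntra = 0.5, pInter = 0.7, seed = 13)
  rep <- scores(infScoresMultilayer(m, normalization = "raw"))
  agg <- scores(infScoresMultilayer(m, normalization = "raw",
                                    aggregate = TRUE))
  phys <- sub("^[^:]*::", "", names(rep))
  expect_equal(unname(agg[unique(phys)]),
               as.numeric(tapply(rep, phys, sum)[unique(phys)]),
               tolerance = 1e-12)
})

test_that("top-k selection is deterministic with identifier tie-breaking", {
  g <- kiteNetwork()
  st <- infScores(g)
  expect_equal(topK(st, 1), "Diane")
  expect_equal(topK(st, 4), c("Diane", "Ike", "Fernando", "Garth"))
  flat <- new("ScoreTable", method = "x", params = list(),
              scores = c(b = 1, a = 1, c = 1))
  expect_equal(topK(flat, 3), c("a", "b", "c"))
  expect_error(topK(st, 0), "positive")
  expect_error(topK(st, 11), "exceeds")
})
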