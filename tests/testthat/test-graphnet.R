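pathGraph3 <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  asBinaryGraph(A)
}

completeGraph <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0
  asBinaryGraph(A)
}

test_that("connectivity matrix construction and degenerate input", {
  # identical series are rejected as constant-free but perfectly correlated
  x <- sin(seq(0, 10, length.out = 30))
  ts <- new("NodeTimeSeries", values = cbind(x, x, x), trSeconds = 2.5)
  conn <- suppressWarnings(buildConnectivity(ts))
  expect_true(all(abs(corValues(conn) - 1) < 1e-12))

  # antiphase sinusoids give r = -1
  ts2 <- new("NodeTimeSeries", values = cbind(x, -x), trSeconds = 2.5)
  conn2 <- suppressWarnings(buildConnectivity(ts2))
  expect_equal(corValues(conn2)[1, 2], -1)

  # constant node names the offender
  bad <- new("NodeTimeSeries",
             values = cbind(a = x, b = rep(1, 30)), trSeconds = 2.5)
  expect_error(buildConnectivity(bad), "b")
})

test_that("thresholding is strict, symmetric, and ignores negative r", {
  r <- matrix(c(1, 0.3, 0.1, -0.5,
                0.3, 1, 0.2, 0.25,
                0.1, 0.2, 1, 0.05,
                -0.5, 0.25, 0.05, 1), 4, 4)
  z <- fisherZ(r * (1 - diag(4)))
  conn <- new("ConnectivityMatrix", r = r, z = z,
              nodeIds = paste0("n", 1:4))
  g <- thresholdGraph(conn, 0.2)
  expect_equal(g@adjacency[1, 2], 1)   # 0.3 survives
  expect_equal(g@adjacency[1, 3], 0)   # 0.1 does not
  expect_equal(g@adjacency[2, 3], 0)   # exactly at threshold: excluded
  expect_equal(g@adjacency[1, 4], 0)   # negative never an edge
  expect_true(all(g@adjacency == t(g@adjacency)))
  expect_equal(sum(diag(g@adjacency)), 0)
  # threshold above all |r| gives an empty graph
  expect_equal(sum(thresholdGraph(conn, 0.999)@adjacency), 0)
})

test_that("hand-checkable metric values", {
  k4 <- completeGraph(4)
  expect_equal(as.numeric(characteristicPathLength(k4)), 1)
  expect_equal(globalEfficiency(k4), 1)
  expect_equal(meanDegree(k4), 3)
  expect_equal(meanBetweenness(k4), 0)

  p3 <- pathGraph3()
  expect_equal(as.numeric(characteristicPathLength(p3)), 4 / 3)
  expect_equal(globalEfficiency(p3), 5 / 6)
  # node B carries the single A-C geodesic: fractional betweenness 1
  expect_equal(meanBetweenness(p3, raw = TRUE)[2], 1)
  expect_equal(meanBetweenness(p3), 1 / 3)

  # star with 5 leaves: center carries all leaf-pair geodesics
  A <- matrix(0, 6, 6); A[1, 2:6] <- 1; A[2:6, 1] <- 1
  star <- asBinaryGraph(A)
  expect_equal(meanBetweenness(star, raw = TRUE)[1], 10)  # C(5,2) pairs
  bw <- meanBetweenness(star, raw = TRUE) / (5 * 4 / 2)
  expect_equal(bw[1], 1)                                   # maximal center

  # two disjoint edges: cross-component pairs excluded and flagged
  A2 <- matrix(0, 4, 4); A2[1, 2] <- A2[2, 1] <- A2[3, 4] <- A2[4, 3] <- 1
  pl <- characteristicPathLength(asBinaryGraph(A2))
  expect_equal(as.numeric(pl), 1)
  expect_equal(attr(pl, "n_unreachable_pairs"), 8L)
  expect_equal(globalEfficiency(asBinaryGraph(A2)), 4 / 12)

  empty <- asBinaryGraph(matrix(0, 3, 3))
  expect_equal(globalEfficiency(empty), 0)
  expect_error(characteristicPathLength(empty), "no reachable pair")
})

test_that("all metrics match brute-force enumeration on small random graphs", {
  set.seed(11)
  for (i in 1:120) {
    n <- sample(3:8, 1)
    A <- randomAdjacency(n, runif(1, 0.2, 0.8))
    g <- asBinaryGraph(A)
    if (any(rowSums(A) > 0) && any(is.finite(bfDistances(A)[upper.tri(A)]))) {
      expect_equal(as.numeric(characteristicPathLength(g)), bfPathLength(A),
                   tolerance = 1e-12)
    }
    expect_equal(globalEfficiency(g), bfEfficiency(A), tolerance = 1e-12)
    expect_equal(meanDegree(g), mean(rowSums(A)), tolerance = 1e-12)
    expect_equal(meanBetweenness(g), bfMeanBetweenness(A), tolerance = 1e-12)
  }
})

test_that("Louvain modularity is seeded, matches Q formula and the exhaustive optimum", {
  # two disconnected triangles: optimal partition has Q = 0.5
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  g <- asBinaryGraph(A)
  res <- modularityQ(g, seed = 1)
  expect_equal(res$Q, 0.5, tolerance = 1e-12)
  expect_equal(bfBestModularity(A), 0.5, tolerance = 1e-12)
  expect_equal(bfModularity(A, res$membership), res$Q, tolerance = 1e-12)

  # complete graph: no community structure
  k6 <- completeGraph(6)
  expect_lt(modularityQ(k6, seed = 2)$Q, 1e-9)

  # seeded determinism
  set.seed(999)
  A2 <- randomAdjacency(12, 0.3)
  g2 <- asBinaryGraph(A2)
  r1 <- modularityQ(g2, seed = 7)
  r2 <- modularityQ(g2, seed = 7)
  expect_identical(r1, r2)
  # reported Q always matches the direct formula on the partition
  expect_equal(bfModularity(A2, r1$membership), r1$Q, tolerance = 1e-12)
})

test_that("hierarchy exponent recovers a planted power law", {
  # graph stitched so that clustering falls with degree; check sign and the
  # degenerate-input path
  set.seed(12)
  A <- randomAdjacency(40, 0.25)
  g <- asBinaryGraph(A)
  beta <- hierarchyBeta(g)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  k <- igraph::degree(ig)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  sel <- k > 1 & cc > 0
  oracle <- -unname(coef(lm(log(cc[sel]) ~ log(k[sel])))[2])
  expect_equal(as.numeric(beta), oracle, tolerance = 1e-10)

  expect_true(is.na(hierarchyBeta(asBinaryGraph(matrix(0, 4, 4)))))
})

test_that("raising the threshold never increases degree or efficiency", {
  set.seed(13)
  x <- matrix(rnorm(60 * 20), 60, 20)
  conn <- buildConnectivity(new("NodeTimeSeries", values = x,
                                trSeconds = 2.5))
  sweep <- graphMetricsSweep(conn, thresholds = c(0.1, 0.2, 0.3, 0.4),
                             seed = 1)
  expect_true(all(diff(sweep$mean_degree) <= 1e-12))
  expect_true(all(diff(sweep$global_efficiency) <= 1e-12))
})

test_that("scalar metrics are invariant to node permutation", {
  set.seed(14)
  x <- matrix(rnorm(80 * 15), 80, 15)
  conn <- buildConnectivity(new("NodeTimeSeries", values = x,
                                trSeconds = 2.5))
  perm <- sample(15)
  connP <- buildConnectivity(new("NodeTimeSeries", values = x[, perm],
                                 trSeconds = 2.5))
  for (thr in c(0.15, 0.25)) {
    g <- thresholdGraph(conn, thr)
    gP <- thresholdGraph(connP, thr)
    expect_equal(as.numeric(characteristicPathLength(g)),
                 as.numeric(characteristicPathLength(gP)), tolerance = 1e-12)
    expect_equal(globalEfficiency(g), globalEfficiency(gP),
                 tolerance = 1e-12)
    expect_equal(meanDegree(g), meanDegree(gP), tolerance = 1e-12)
    expect_equal(meanBetweenness(g), meanBetweenness(gP), tolerance = 1e-12)
  }
})

test_that("a full-size synthetic subject yields a 499 x 499 matrix", {
  parc <- defaultParcellation()
  coh <- generateCohort(2, seed = 21)
  ts <- generateNodeTimeSeries(coh$subjects[1, ], parc, coh$truth,
                               nVolumes = 50, seed = 1)
  conn <- buildConnectivity(ts)
  expect_identical(dim(corValues(conn)), c(499L, 499L))
})
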