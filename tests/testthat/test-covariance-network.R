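test_that("a 12x22 group table yields a 22x22 unit-diagonal network", {
  tabs <- generateMouseCohort(mouseCohortSpec(seed = 3))
  net <- buildCovarianceNetwork(tabs$groupA, group = "EP", nPerm = 500,
                                seed = 1)
  r <- correlationMatrix(net)
  expect_identical(dim(r), c(22L, 22L))
  expect_true(all(diag(r) == 1))
  expect_equal(r, t(r), tolerance = 1e-12)
  p <- edgePValues(net)
  expect_true(all(p[upper.tri(p)] > 0 & p[upper.tri(p)] <= 1))
  # identical seed reproduces identical p matrices
  net2 <- buildCovarianceNetwork(tabs$groupA, group = "EP", nPerm = 500,
                                 seed = 1)
  expect_identical(edgePValues(net2), p)
})

test_that("a duplicated region column gives r = 1 at the minimum attainable p", {
  tab <- withr::with_seed(2, matrix(rnorm(12 * 5), 12, 5))
  tab <- cbind(tab, tab[, 5] )
  colnames(tab) <- paste0("reg", 1:6)
  net <- buildCovarianceNetwork(tab, nPerm = 400, seed = 3)
  expect_equal(correlationMatrix(net)["reg5", "reg6"], 1, tolerance = 1e-12)
  expect_equal(edgePValues(net)["reg5", "reg6"], 1 / 401, tolerance = 1e-12)
})

test_that("degenerate SUV tables are rejected with informative errors", {
  tab <- withr::with_seed(4, matrix(rnorm(24), 6, 4,
                                    dimnames = list(NULL, paste0("reg", 1:4))))
  tab[, 2] <- 5
  expect_error(buildCovarianceNetwork(tab, nPerm = 10, seed = 1), "reg2")
  expect_error(buildCovarianceNetwork(tab[1:3, -2], nPerm = 10, seed = 1),
               "at least 4")
})

test_that("thresholded variants nest and densities follow", {
  withr::with_seed(5, {
    for (i in 1:10) {
      tab <- matrix(rnorm(10 * 8), 10, 8)
      net <- buildCovarianceNetwork(tab, nPerm = 200, seed = i)
      t05 <- thresholdedMatrix(net, 0.05)
      t01 <- thresholdedMatrix(net, 0.01)
      expect_true(all(t01[t01 != 0] == t05[t01 != 0]))  # 0.01 edges survive 0.05
      p05 <- suppressWarnings(networkProperties(net, 0.05))
      p01 <- suppressWarnings(networkProperties(net, 0.01))
      expect_lte(p01@density, p05@density)
      expect_identical(p05@density, sum(p05@degree) %/% 2L)
    }
  })
})

test_that("metrics on a complete positive unit-weight graph are exact", {
  W <- matrix(1, 4, 4); diag(W) <- 0
  props <- networkProperties(fakeNetwork(W), 0.05)
  expect_identical(props@degree, rep(3L, 4))
  expect_identical(props@density, 6L)
  expect_equal(props@clustering, rep(1, 4), tolerance = 1e-12)
  expect_equal(props@strengthPos, rep(3, 4))
  expect_equal(props@strengthNeg, rep(0, 4))
})

test_that("signed clustering matches brute-force triangle enumeration", {
  withr::with_seed(6, {
    for (i in 1:20) {
      W <- matrix(0, 5, 5)
      vals <- runif(10, -1, 1) * rbinom(10, 1, 0.7)
      W[upper.tri(W)] <- vals
      W <- W + t(W)
      props <- networkProperties(fakeNetwork(W), 0.05)
      expect_equal(props@clustering, bruteForceSignedClustering(W),
                   tolerance = 1e-12)
      expect_identical(props@density, sum(W[upper.tri(W)] != 0))
      expect_equal(unname(props@strengthNeg),
                   sapply(1:5, function(n) sum(abs(pmin(W[n, ], 0)))))
    }
  })
})

test_that("top-quartile hub sets follow quartile arithmetic", {
  # 4 nodes with distinct strengths: exactly one strength hub
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.9
  W[1, 3] <- W[3, 1] <- 0.5
  W[1, 4] <- W[4, 1] <- 0.2
  props <- networkProperties(fakeNetwork(W), 0.05)
  expect_identical(props@hubsStrength, "n01")
  # degree ties are all included
  expect_setequal(props@hubsDegree, "n01")
})

test_that("an empty thresholded network warns and reports zero metrics", {
  W <- matrix(0, 4, 4)
  expect_warning(props <- networkProperties(fakeNetwork(W), 0.05), "no edges")
  expect_identical(props@density, 0L)
  expect_true(all(props@clustering == 0))
  expect_length(props@hubsStrength, 0L)
})

test_that("edge-distribution KS comparison matches a hand-computed CDF gap", {
  tabs <- generateMouseCohort(mouseCohortSpec(seed = 7))
  netA <- buildCovarianceNetwork(tabs$groupA, nPerm = 100, seed = 1)
  expect_equal(compareEdgeDistributions(netA, netA)$statistic, 0)
  # disjoint weight ranges -> maximal statistic
  W1 <- matrix(0, 5, 5); W1[upper.tri(W1)] <- seq(0.1, 0.3, length.out = 10)
  W2 <- matrix(0, 5, 5); W2[upper.tri(W2)] <- seq(0.6, 0.9, length.out = 10)
  n1 <- fakeNetwork(W1 + t(W1)); n2 <- fakeNetwork(W2 + t(W2))
  expect_equal(compareEdgeDistributions(n1, n2)$statistic, 1)
  # 10-edge toy vectors: statistic equals the max empirical-CDF gap
  e1 <- (W1 + t(W1))[upper.tri(W1)]
  e2 <- (W2 + t(W2))[upper.tri(W2)]
  gap <- max(sapply(sort(c(e1, e2)), function(t)
    abs(mean(e1 <= t) - mean(e2 <= t))))
  expect_equal(compareEdgeDistributions(n1, n2)$statistic, gap)
  expect_error(compareEdgeDistributions(n1, netA), "region")
})

test_that("between-group edge tests are symmetric in group labels", {
  tabs <- generateMouseCohort(mouseCohortSpec(nPerGroup = 8, nRegions = 6,
                                              seed = 8))
  p1 <- compareEdgesBetweenGroups(tabs$groupA, tabs$groupB, nPerm = 400,
                                  seed = 9)
  p2 <- compareEdgesBetweenGroups(tabs$groupB, tabs$groupA, nPerm = 400,
                                  seed = 9)
  # the observed statistic is exactly antisymmetric; Monte-Carlo p-values
  # agree up to permutation-sampling noise
  expect_equal(attr(p1, "observedDiff"), -attr(p2, "observedDiff"),
               tolerance = 1e-12)
  expect_lt(max(abs(p1[upper.tri(p1)] - p2[upper.tri(p2)])), 0.12)
  expect_true(all(p1[upper.tri(p1)] >= 1 / 401))
  expect_warning(compareEdgesBetweenGroups(tabs$groupA[1:3, ],
                                           tabs$groupB[1:3, ],
                                           nPerm = 10, seed = 1), "group sizes")
})

test_that("a planted covariance block is flagged by the edge permutation test", {
  bl <- list(list(regions = 1:2, r = 0.9))
  tabs <- generateMouseCohort(mouseCohortSpec(nPerGroup = 50, seed = 10),
                              blockStructureB = bl)
  p <- compareEdgesBetweenGroups(tabs$groupA, tabs$groupB, nPerm = 500,
                                 seed = 11)
  expect_lt(p[1, 2], 0.05)
  expect_gt(median(p[upper.tri(p)][-1]), p[1, 2])
})
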