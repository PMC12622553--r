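test_that("density estimates use a 512-point grid and integrate to one", {
  x <- withr::with_seed(1, rnorm(500))
  d <- estimateDensity(x)
  expect_length(d@grid, 512L)
  integral <- sum(diff(d@grid) * (head(d@density, -1) + tail(d@density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_true(all(d@density >= d@epsilon))
})

test_that("the KDE recovers a standard Gaussian pdf", {
  x <- withr::with_seed(2, rnorm(10000))
  d <- estimateDensity(x)
  expect_lt(abs(d@grid[which.max(d@density)]), 0.1)     # mode near 0
  expect_lt(max(abs(d@density - dnorm(d@grid))), 0.02)  # closed-form oracle
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(estimateDensity(rep(1, 50)), "degenerate|constant")
  expect_error(estimateDensity(rnorm(5)), "at least 10")
  expect_error(estimateDensity(rnorm(100), nGrid = 100), "power of two")
  expect_error(estimateDensity(rnorm(100), nGrid = 32), "nGrid")
})

test_that("symmetric KL on discrete masses matches the hand-evaluated value", {
  P <- c(0.5, 0.5); Q <- c(0.9, 0.1)
  # independent evaluation of the defining sum, natural log
  oracle <- 0.5 * log(5 / 9) + 0.5 * log(5) + 0.9 * log(1.8) + 0.1 * log(0.2)
  expect_equal(klDivergenceSym(P, Q), oracle, tolerance = 1e-6)
  expect_equal(klDivergenceSym(P, Q), 0.8789, tolerance = 1e-4)
  expect_equal(klSimilarity(P, Q), exp(-oracle), tolerance = 1e-6)
  expect_equal(klSimilarity(P, Q), 0.4152, tolerance = 5e-4)
})

test_that("symmetric KL is zero iff the distributions coincide, and symmetric", {
  expect_identical(klDivergenceSym(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_identical(klSimilarity(c(0.3, 0.7), c(0.3, 0.7)), 1)
  withr::with_seed(3, {
    for (i in 1:100) {
      p <- runif(8); q <- runif(8)
      expect_identical(klDivergenceSym(p, q), klDivergenceSym(q, p))
      expect_gte(klDivergenceSym(p, q), 0)
    }
  })
})

test_that("KLS of density estimates lies in (0, 1] and honors the identity case", {
  x <- withr::with_seed(4, rnorm(200))
  d1 <- estimateDensity(x)
  expect_identical(klSimilarity(d1, d1), 1)
  d2 <- estimateDensity(x + 1, from = min(d1@grid), to = max(d1@grid))
  s <- klSimilarity(d1, d2)
  expect_gt(s, 0); expect_lt(s, 1)
  d3 <- estimateDensity(rnorm(100))  # different grid
  expect_error(klDivergenceSym(d1, d3), "grid")
})

test_that("similarity matrices are symmetric, unit-diagonal and match a per-pair oracle", {
  samples <- withr::with_seed(5, list(a = rnorm(80, 0), b = rnorm(80, 0),
                                      c = rnorm(80, 3)))
  m <- buildSimilarityMatrix(ROISampleSet("s1", samples))
  v <- similarityValues(m)
  expect_identical(dim(v), c(3L, 3L))
  expect_true(all(diag(v) == 1))
  expect_equal(v, t(v), tolerance = 1e-12)
  # closer means -> higher similarity
  expect_gt(v["a", "b"], v["a", "c"])
  # every entry equals a standalone re-evaluation of the defining formulas
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(v[i, j], oracleKLS(samples[[i]], samples[[j]]),
                 tolerance = 1e-10)
})

test_that("identical ROI samples give an all-ones similarity matrix", {
  x <- withr::with_seed(6, rnorm(60))
  m <- buildSimilarityMatrix(ROISampleSet("s", list(r1 = x, r2 = x, r3 = x)))
  expect_true(all(similarityValues(m) == 1))
})

test_that("a failing ROI is reported by name", {
  expect_error(
    buildSimilarityMatrix(ROISampleSet("s", list(ok = rnorm(50),
                                                 flat = rep(2, 50)))),
    "flat")
})

test_that("KLS never increases with mean separation (monotonicity)", {
  x <- withr::with_seed(7, rnorm(150))
  seps <- seq(0, 3, by = 0.5)
  kls <- vapply(seps, function(s) {
    set <- ROISampleSet("s", list(a = x, b = x + s))
    similarityValues(buildSimilarityMatrix(set))[1, 2]
  }, numeric(1L))
  expect_true(all(diff(kls) <= 1e-12))
})

test_that("relabeling ROIs permutes the matrix rows and columns identically", {
  samples <- withr::with_seed(9, lapply(1:4, function(i) rnorm(60, i / 2)))
  names(samples) <- paste0("r", 1:4)
  m1 <- similarityValues(buildSimilarityMatrix(ROISampleSet("s", samples)))
  perm <- c(3L, 1L, 4L, 2L)
  m2 <- similarityValues(buildSimilarityMatrix(ROISampleSet("s", samples[perm])))
  expect_equal(m2, m1[perm, perm], tolerance = 1e-12)
})
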