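probeRow <- function(probe, gene, donor, region, intensity, background = 100) {
  data.frame(probe_id = probe, gene_symbol = gene, donor_id = donor,
             region_id = region, intensity = intensity,
             background = background, stringsAsFactors = FALSE)
}

test_that("intensity filtering removes a probe only when below threshold everywhere", {
  t <- rbind(
    probeRow("p1", "g1", "d1", c("r1", "r2"), c(200, 300)),        # well above
    probeRow("p2", "g2", "d1", c("r1", "r2"), c(150, 150)),        # exactly 1.5x
    probeRow("p3", "g3", "d1", c("r1", "r2"), c(100, 120)),        # below everywhere
    probeRow("p4", "g4", "d1", c("r1", "r2"), c(100, 200)))        # below in half
  out <- filterProbesIntensity(t)
  expect_setequal(unique(out$probe_id), c("p1", "p2", "p4"))
  # all-pass table is unchanged
  ok <- rbind(probeRow("p1", "g1", "d1", c("r1", "r2"), c(200, 300)))
  expect_identical(filterProbesIntensity(ok), ok)
})

test_that("differential stability keeps the most donor-consistent probe per gene", {
  profile <- c(1, 3, 2, 5, 4)
  regions <- paste0("r", 1:5)
  keptA <- withr::with_seed(10, replicate(20, {
    t <- do.call(rbind, lapply(paste0("d", 1:3), function(d) rbind(
      probeRow("pA", "g1", d, regions, profile),                 # DS = 1
      probeRow("pB", "g1", d, regions, rnorm(5, 10)))))          # noise
    attr(collapseProbesDS(t), "stability")$probe_id
  }))
  expect_gte(mean(keptA == "pA"), 0.95)
  # explicit pairwise-Spearman oracle for the replicated probe
  t <- do.call(rbind, lapply(paste0("d", 1:3), function(d)
    probeRow("pA", "g1", d, regions, profile)))
  expect_equal(attr(collapseProbesDS(rbind(t,
    probeRow("pB", "g1", "d1", regions, 5:1),
    probeRow("pB", "g1", "d2", regions, c(2, 1, 4, 3, 5)))),
    "stability")$ds[1], 1)
})

test_that("single-probe genes keep their probe and exact ties break lexicographically", {
  regions <- paste0("r", 1:4)
  t <- do.call(rbind, lapply(c("d1", "d2"), function(d) rbind(
    probeRow("only", "gSolo", d, regions, c(1, 2, 3, 4)),
    probeRow("pZ", "gTie", d, regions, c(4, 3, 2, 1)),
    probeRow("pA", "gTie", d, regions, c(4, 3, 2, 1)))))   # identical to pZ
  out <- collapseProbesDS(t)
  stab <- attr(out, "stability")
  expect_identical(stab$probe_id[stab$gene_symbol == "gSolo"], "only")
  expect_identical(stab$probe_id[stab$gene_symbol == "gTie"], "pA")
})

test_that("a gene with no probe measurable in two donors is dropped with a warning", {
  regions <- paste0("r", 1:4)
  t <- rbind(
    do.call(rbind, lapply(c("d1", "d2"), function(d)
      probeRow("pG", "gOK", d, regions, c(1, 2, 3, 4)))),
    probeRow("pX", "gBad", "d1", regions, c(1, 2, 3, 4)),
    probeRow("pY", "gBad", "d2", "r9", 1))
  expect_warning(out <- collapseProbesDS(t), "gBad")
  expect_false("gBad" %in% attr(out, "stability")$gene_symbol)
})

test_that("scaled robust sigmoid matches a step-by-step evaluation", {
  x <- c(1, 2, 3, 4, 100)
  med <- median(x); iqr <- IQR(x)
  oracle <- 1 / (1 + exp(-(x - med) / (iqr / 1.35)))
  oracle01 <- (oracle - min(oracle)) / (max(oracle) - min(oracle))
  expect_equal(srsNormalize(x), oracle01, tolerance = 1e-12)
  expect_equal(srsNormalize(x, rescale = FALSE), oracle, tolerance = 1e-12)
  # the median maps to the sigmoid midpoint before rescaling
  expect_equal(srsNormalize(x, rescale = FALSE)[3], 0.5, tolerance = 1e-12)
  # monotone input gives monotone (rank-preserving) output
  y <- withr::with_seed(1, sort(rnorm(20)))
  expect_true(all(diff(srsNormalize(y)) > 0))
  expect_error(srsNormalize(c(1, 1, 1, 1, 9)), "IQR")
})

test_that("the probe pipeline assembles a normalized expression matrix", {
  spec <- geneMatrixSpec(nRegions = 10, nGenes = 6, nDonors = 3,
                         probesPerGene = 2, nPlantedPos = 2, plantedR = 0.8,
                         seed = 4)
  gm <- generateGeneMatrix(spec, withr::with_seed(2, rnorm(10)))
  mat <- buildExpressionMatrix(gm$probes)
  expect_identical(dim(mat), c(10L, 6L))
  expect_true(attr(mat, "srsApplied"))
  expect_true(all(mat >= 0 & mat <= 1))
  expect_true(all(apply(mat, 2, sd) > 0))
})

test_that("gene-map correlations match the textbook Pearson formula", {
  x <- c(2.1, 3.5, 1.2, 4.4, 5.0, 2.8, 3.9, 0.7, 4.1, 3.3)
  y <- c(1.0, 2.2, 0.8, 3.9, 4.8, 2.0, 3.1, 1.1, 3.7, 2.9)
  res <- geneMapCorrelation(x, y)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  expect_equal(geneMapCorrelation(y, y)$r, 1, tolerance = 1e-12)
  expect_equal(geneMapCorrelation(-y, y)$r, -1, tolerance = 1e-12)
  expect_error(geneMapCorrelation(rep(1, 10), y), "constant")
})
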