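test_that("human cohort generation is deterministic under a fixed seed", {
  a <- smallCohort(seed = 7L)
  b <- smallCohort(seed = 7L)
  expect_identical(a, b)
  c <- smallCohort(seed = 8L)
  expect_false(identical(a$subjects[[1L]]@samples, c$subjects[[1L]]@samples))
})

test_that("adding subjects to one arm leaves existing subjects unchanged", {
  small <- generateHumanCohort(humanCohortSpec(3, 3, nRoi = 4, seed = 11))
  big <- generateHumanCohort(humanCohortSpec(5, 3, nRoi = 4, seed = 11))
  expect_identical(small$subjects[[1L]]@samples, big$subjects[[1L]]@samples)
  expect_identical(small$subjects[[4L]]@samples,  # first control
                   big$subjects[[6L]]@samples)
})

test_that("cohort dimensions follow the spec (246 ROIs x 200 voxels)", {
  co <- generateHumanCohort(humanCohortSpec(2, 2, seed = 1))
  expect_length(co$subjects, 4L)
  for (s in co$subjects) {
    expect_length(s@samples, 246L)
    expect_true(all(lengths(s@samples) == 200L))
  }
  expect_named(co$design, c("subject_id", "group", "age", "sex"))
  expect_true(all(co$design$age >= 18 & co$design$age <= 60))
})

test_that("planted deficit shifts the case voxel mean by effectShift SDs", {
  # oracle: pooled sample means over ~10,000 draws per arm
  spec <- humanCohortSpec(nCases = 25, nControls = 25, nRoi = 3,
                          voxelsPerRoi = 400, effectRois = 1L,
                          effectShift = -1, noiseSd = 0.1, seed = 42)
  co <- generateHumanCohort(spec)
  grab <- function(idx, roi) unlist(lapply(co$subjects[idx],
                                           function(s) s@samples[[roi]]))
  diff1 <- mean(grab(1:25, 1)) - mean(grab(26:50, 1))
  expect_equal(diff1, -1 * 0.1, tolerance = 0.05)
  diff2 <- mean(grab(1:25, 2)) - mean(grab(26:50, 2))
  expect_lt(abs(diff2), 0.01)  # unaffected ROI
})

test_that("invalid human cohort specs fail naming the offending field", {
  expect_error(humanCohortSpec(1, 5, seed = 1), "nCases")
  expect_error(humanCohortSpec(5, 5, voxelsPerRoi = 5, seed = 1), "voxelsPerRoi")
  expect_error(humanCohortSpec(5, 5, noiseSd = -1, seed = 1), "noiseSd")
  expect_error(humanCohortSpec(5, 5, nRoi = 4, effectRois = 9, seed = 1),
               "effectRois")
})

test_that("planted genes correlate with the target map at the requested level", {
  spec <- geneMatrixSpec(nRegions = 246, nGenes = 300, nPlantedPos = 10,
                         nPlantedNeg = 10, plantedR = 0.8, seed = 5)
  map <- withr::with_seed(99, rnorm(246))
  gm <- generateGeneMatrix(spec, map)
  expect_identical(dim(gm$expression), c(246L, 300L))
  rs <- cor(gm$expression, map)
  pos <- gm$planted$gene[gm$planted$direction == 1L]
  neg <- gm$planted$gene[gm$planted$direction == -1L]
  expect_true(all(rs[pos, 1] > 0.7 & rs[pos, 1] < 0.9))
  expect_true(all(rs[neg, 1] < -0.7 & rs[neg, 1] > -0.9))
  # pure-noise case: correlations consistent with the null
  gm0 <- generateGeneMatrix(geneMatrixSpec(nRegions = 246, nGenes = 300,
                                           seed = 6), map)
  rs0 <- cor(gm0$expression, map)
  expect_lt(max(abs(rs0)), 5 / sqrt(246))
})

test_that("the full-size gene matrix has 5451 gene columns", {
  spec <- geneMatrixSpec(nRegions = 50, nGenes = 5451, seed = 2)
  gm <- generateGeneMatrix(spec, seq_len(50))
  expect_identical(ncol(gm$expression), 5451L)
})

test_that("gene matrix generation rejects a constant target map", {
  spec <- geneMatrixSpec(nRegions = 10, nGenes = 20, seed = 1)
  expect_error(generateGeneMatrix(spec, rep(1, 10)), "constant")
  expect_error(generateGeneMatrix(spec, 1:5), "length")
})

test_that("probe-level output carries donors, redundant probes and background", {
  spec <- geneMatrixSpec(nRegions = 8, nGenes = 5, nDonors = 3,
                         probesPerGene = 2, seed = 3)
  gm <- generateGeneMatrix(spec, rnorm(8))
  probes <- gm$probes
  expect_s3_class(probes, "data.frame")
  expect_setequal(unique(probes$donor_id), c("D01", "D02", "D03"))
  expect_identical(nrow(probes), 8L * 5L * 3L * 2L)
  expect_true(all(probes$background > 0))
  expect_identical(length(unique(probes$probe_id)), 10L)
})

test_that("mouse cohort tables have the stated dimensions and are seeded", {
  tabs <- generateMouseCohort(mouseCohortSpec(seed = 3))
  expect_identical(dim(tabs$groupA), c(12L, 22L))
  expect_identical(dim(tabs$groupB), c(12L, 22L))
  expect_identical(tabs, generateMouseCohort(mouseCohortSpec(seed = 3)))
})

test_that("mouse covariance structure matches the spec blocks", {
  # null structure: weak empirical correlations at large n
  t0 <- generateMouseCohort(mouseCohortSpec(nPerGroup = 200, seed = 4))
  r0 <- cor(t0$groupA)
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.1)
  # planted block at 0.9: empirical r in [0.85, 0.95] (sample-correlation oracle)
  bl <- list(list(regions = c(1, 2), r = 0.9))
  t1 <- generateMouseCohort(mouseCohortSpec(nPerGroup = 200,
                                            blockStructure = bl, seed = 5))
  expect_gt(cor(t1$groupA)[1, 2], 0.85)
  expect_lt(cor(t1$groupA)[1, 2], 0.95)
})

test_that("a non-positive-semi-definite block structure is rejected", {
  bad <- list(list(regions = 1:3, r = -0.9))
  expect_error(mouseCohortSpec(blockStructure = bad, seed = 1),
               "positive semi-definite")
  expect_error(mouseCohortSpec(blockStructure = list(list(regions = 1:2, r = 1.2)),
                               seed = 1), "blockStructure")
})
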