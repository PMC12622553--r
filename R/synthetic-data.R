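#' @include AllClasses.R
NULL

# Derive a per-subject substream seed from the cohort seed. Cases and controls
# occupy disjoint index spaces so adding subjects to one arm never perturbs
# the other; all seeds stay below 2^31.
.subjectSeed <- function(seed, arm, i) {
  base <- (seed * 1009L) %% 1000000007L
  offset <- if (arm == "case") 0L else 500000L
  (base + offset + i) %% 2147483647L
}

#' Generate a synthetic two-group human PET cohort
#'
#' Draws per-ROI voxel-level uptake samples for cases and controls. Each ROI
#' has a cohort-level baseline mean (Gaussian across ROIs around a typical
#' SUVR of 1.2); voxel values are Gaussian around that baseline with standard
#' deviation \code{noiseSd}. In \code{effectRois}, case distributions are
#' shifted by \code{effectShift * noiseSd} (i.e. the shift is expressed in SD
#' units of the control voxel distribution). Ages are uniform on [18, 60] and
#' sex is Bernoulli(0.5), independent of group unless \code{ageConfound > 0},
#' which shifts case ages upward to exercise covariate adjustment.
#'
#' One global seed expands into per-subject substreams, so enlarging one arm
#' leaves already-generated subjects unchanged.
#'
#' @param spec a \code{\link{humanCohortSpec}}.
#' @return list with \code{subjects} (list of \code{\linkS4class{ROISampleSet}},
#'   cases first) and \code{design} (data.frame with subject_id, group, age,
#'   sex).
#' @examples
#' cohort <- generateHumanCohort(humanCohortSpec(4, 4, nRoi = 6, seed = 7))
#' cohort$design
#' @export
generateHumanCohort <- function(spec) {
  stopifnot(is(spec, "HumanCohortSpec"))
  validObject(spec)
  roiLabels <- sprintf("ROI%03d", seq_len(spec@nRoi))
  baseline <- withSeed(spec@seed,
    rnorm(spec@nRoi, mean = 1.2, sd = 0.15))
  baseline <- pmax(baseline, 0.2)

  drawSubject <- function(arm, i) {
    id <- sprintf("%s%03d", if (arm == "case") "case" else "ctrl", i)
    shift <- numeric(spec@nRoi)
    if (arm == "case" && length(spec@effectRois))
      shift[spec@effectRois] <- spec@effectShift * spec@noiseSd
    samples <- withSeed(.subjectSeed(spec@seed, arm, i), {
      lapply(seq_len(spec@nRoi), function(r)
        rnorm(spec@voxelsPerRoi, mean = baseline[r] + shift[r],
              sd = spec@noiseSd))
    })
    names(samples) <- roiLabels
    ROISampleSet(id, samples)
  }

  cases <- lapply(seq_len(spec@nCases), function(i) drawSubject("case", i))
  controls <- lapply(seq_len(spec@nControls), function(i) drawSubject("control", i))
  subjects <- c(cases, controls)

  n <- spec@nCases + spec@nControls
  design <- withSeed((spec@seed * 31L + 17L) %% 2147483647L, {
    age <- runif(n, 18, 60)
    isCase <- rep(c(TRUE, FALSE), c(spec@nCases, spec@nControls))
    if (spec@ageConfound > 0)
      age[isCase] <- pmin(age[isCase] + spec@ageConfound * 42, 60)
    data.frame(
      subject_id = vapply(subjects, function(s) s@subjectId, character(1L)),
      group = factor(ifelse(isCase, "case", "control"),
                     levels = c("control", "case")),
      age = age,
      sex = factor(sample(c("F", "M"), n, replace = TRUE)),
      stringsAsFactors = FALSE)
  })
  list(subjects = subjects, design = design)
}

#' Generate a synthetic regions-by-genes expression matrix
#'
#' Planted genes are linear blends \eqn{r z(map) + \sqrt{1-r^2}\,\epsilon} of
#' the z-scored target map and independent Gaussian noise, so their expected
#' Pearson correlation with the map is \code{+plantedR} (positive set) or
#' \code{-plantedR} (negative set); all remaining genes are independent noise.
#' When \code{probesPerGene > 1} or \code{nDonors > 1} a probe-level long
#' table is also returned: each probe replicates its gene's regional profile
#' plus donor and probe noise, on a microarray-like intensity scale with a
#' per-measurement background level, ready for the probe-collapse and
#' intensity-filter stages.
#'
#' @param spec a \code{\link{geneMatrixSpec}}.
#' @param targetMap numeric vector of length \code{nRegions}; must not be
#'   constant.
#' @return list with \code{expression} (regions x genes matrix),
#'   \code{planted} (data.frame gene/direction), and \code{probes} (long
#'   data.frame, or NULL when no probe-level structure was requested).
#' @export
generateGeneMatrix <- function(spec, targetMap) {
  stopifnot(is(spec, "GeneMatrixSpec"))
  validObject(spec)
  if (length(targetMap) != spec@nRegions)
    stop("'targetMap' must have length nRegions = ", spec@nRegions)
  if (sd(targetMap) == 0)
    stop("'targetMap' must not be constant")

  R <- spec@nRegions; G <- spec@nGenes
  z <- as.numeric(scale(targetMap))
  genes <- sprintf("G%05d", seq_len(G))
  direction <- rep(0L, G)
  if (spec@nPlantedPos) direction[seq_len(spec@nPlantedPos)] <- 1L
  if (spec@nPlantedNeg)
    direction[spec@nPlantedPos + seq_len(spec@nPlantedNeg)] <- -1L

  out <- withSeed(spec@seed, {
    expr <- matrix(rnorm(R * G, sd = spec@noiseSd), nrow = R)
    for (g in which(direction != 0L)) {
      eps <- rnorm(R)
      expr[, g] <- direction[g] * spec@plantedR * z +
        sqrt(1 - spec@plantedR^2) * eps
    }
    probes <- NULL
    if (spec@probesPerGene > 1L || spec@nDonors > 1L) {
      probes <- .probeLongTable(spec, expr, genes)
    }
    list(expr = expr, probes = probes)
  })
  regionLabels <- names(targetMap)
  if (is.null(regionLabels)) regionLabels <- sprintf("R%03d", seq_len(R))
  dimnames(out$expr) <- list(regionLabels, genes)
  planted <- data.frame(gene = genes[direction != 0L],
                        direction = direction[direction != 0L],
                        stringsAsFactors = FALSE)
  list(expression = out$expr, planted = planted, probes = out$probes)
}

# probe-level replicates: intensity = 100 * 2^(profile + donor + probe noise),
# background drawn near 50 so most planted probes clear the 1.5x filter
.probeLongTable <- function(spec, expr, genes) {
  R <- spec@nRegions
  rows <- vector("list", spec@nGenes * spec@probesPerGene * spec@nDonors)
  k <- 0L
  regionIds <- sprintf("R%03d", seq_len(R))
  for (g in seq_len(spec@nGenes)) {
    for (p in seq_len(spec@probesPerGene)) {
      probeQuality <- if (p == 1L) 0.1 else 0.8  # later probes noisier
      for (d in seq_len(spec@nDonors)) {
        k <- k + 1L
        intensity <- 100 * 2^(expr[, g] + rnorm(1L, sd = 0.2) +
                                rnorm(R, sd = probeQuality))
        rows[[k]] <- data.frame(
          probe_id = sprintf("%s_p%02d", genes[g], p),
          gene_symbol = genes[g],
          donor_id = sprintf("D%02d", d),
          region_id = regionIds,
          intensity = intensity,
          background = runif(R, 40, 60),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic two-group rodent SUV cohort
#'
#' Draws animals-by-regions SUV tables for two groups from multivariate
#' Gaussians sharing the marginal mean and SD but with group-specific
#' block correlation structure (\code{blockStructureB} defaults to the same
#' structure as group A).
#'
#' @param spec a \code{\link{mouseCohortSpec}} describing group A.
#' @param blockStructureB optional block structure for group B (same format as
#'   \code{blockStructure}); defaults to group A's.
#' @return list of two numeric matrices \code{groupA}, \code{groupB}
#'   (\code{nPerGroup} rows, \code{nRegions} columns, with animal and region
#'   dimnames).
#' @examples
#' tabs <- generateMouseCohort(mouseCohortSpec(seed = 3))
#' dim(tabs$groupA)  # 12 x 22
#' @export
generateMouseCohort <- function(spec, blockStructureB = NULL) {
  stopifnot(is(spec, "MouseCohortSpec"))
  validObject(spec)
  specB <- spec
  if (!is.null(blockStructureB)) {
    specB@blockStructure <- blockStructureB
    validObject(specB)
  }
  regions <- sprintf("region%02d", seq_len(spec@nRegions))
  drawGroup <- function(s, label, offset) {
    corr <- .mouseCorrelation(s)
    sigma <- corr * s@suvSd^2
    tab <- withSeed((s@seed * 131L + offset) %% 2147483647L,
      MASS::mvrnorm(s@nPerGroup, mu = rep(s@suvMean, s@nRegions),
                    Sigma = sigma))
    dimnames(tab) <- list(sprintf("%s_%02d", label, seq_len(s@nPerGroup)),
                          regions)
    tab
  }
  list(groupA = drawGroup(spec, "A", 1L), groupB = drawGroup(specB, "B", 2L))
}
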