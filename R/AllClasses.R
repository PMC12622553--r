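#' @import methods
NULL

# ---------------------------------------------------------------------------
# Cohort specification objects (synthetic-data module)
# ---------------------------------------------------------------------------

#' Specification of a synthetic two-group human PET cohort
#'
#' Describes a cohort of cases and controls with per-ROI voxel-level uptake
#' samples. Controls are drawn from ROI-specific Gaussian baselines; cases are
#' identical except in \code{effectRois}, where the distribution location is
#' shifted by \code{effectShift} standard deviations of the control voxel
#' distribution (negative values model synaptic-density deficits).
#'
#' @slot nCases,nControls number of subjects per group (each >= 2).
#' @slot nRoi number of regions of interest (default 246).
#' @slot voxelsPerRoi voxel samples per ROI per subject (default 200, >= 10).
#' @slot effectRois integer indices (1-based) of affected ROIs.
#' @slot effectShift location shift in control-SD units (<= 0 for deficits).
#' @slot noiseSd within-ROI voxel standard deviation (> 0).
#' @slot ageConfound correlation knob in [0,1): fraction of the age range by
#'   which case ages are shifted upward, to exercise covariate adjustment.
#' @slot seed integer RNG seed.
#' @export
setClass("HumanCohortSpec",
  representation(nCases = "integer", nControls = "integer", nRoi = "integer",
                 voxelsPerRoi = "integer", effectRois = "integer",
                 effectShift = "numeric", noiseSd = "numeric",
                 ageConfound = "numeric", seed = "integer"))

setValidity("HumanCohortSpec", function(object) {
  if (object@nCases < 2L) return("invalid 'nCases': must be >= 2")
  if (object@nControls < 2L) return("invalid 'nControls': must be >= 2")
  if (object@nRoi < 1L) return("invalid 'nRoi': must be >= 1")
  if (object@voxelsPerRoi < 10L) return("invalid 'voxelsPerRoi': must be >= 10")
  if (length(object@effectRois) &&
      (min(object@effectRois) < 1L || max(object@effectRois) > object@nRoi))
    return("invalid 'effectRois': indices must lie in 1..nRoi")
  if (object@noiseSd <= 0) return("invalid 'noiseSd': must be > 0")
  if (object@ageConfound < 0 || object@ageConfound >= 1)
    return("invalid 'ageConfound': must be in [0, 1)")
  TRUE
})

#' @rdname HumanCohortSpec-class
#' @param nCases,nControls,nRoi,voxelsPerRoi,effectRois,effectShift,noiseSd,ageConfound,seed
#'   see the corresponding slots.
#' @return a validated \code{HumanCohortSpec}.
#' @examples
#' humanCohortSpec(nCases = 4, nControls = 4, nRoi = 10, seed = 1)
#' @export
humanCohortSpec <- function(nCases, nControls, nRoi = 246L, voxelsPerRoi = 200L,
                            effectRois = integer(), effectShift = 0,
                            noiseSd = 0.1, ageConfound = 0, seed = 1L) {
  new("HumanCohortSpec",
      nCases = .checkCount(nCases, "nCases", 2L),
      nControls = .checkCount(nControls, "nControls", 2L),
      nRoi = .checkCount(nRoi, "nRoi"),
      voxelsPerRoi = .checkCount(voxelsPerRoi, "voxelsPerRoi", 10L),
      effectRois = as.integer(effectRois),
      effectShift = .checkScalar(effectShift, "effectShift"),
      noiseSd = .checkScalar(noiseSd, "noiseSd"),
      ageConfound = .checkScalar(ageConfound, "ageConfound"),
      seed = .checkCount(seed, "seed", 0L))
}

#' Specification of a synthetic regions-by-genes expression matrix
#'
#' A minority of "planted" genes have spatial profiles correlated (positively
#' or negatively, at target correlation \code{plantedR}) with a supplied
#' regional map; the remaining genes are independent noise. Optionally emits a
#' probe-level long table (multiple probes per gene, multiple donors) to
#' exercise the probe-collapse and filtering stages.
#'
#' @slot nRegions,nGenes matrix dimensions.
#' @slot nPlantedPos,nPlantedNeg counts of positively / negatively planted genes.
#' @slot plantedR target absolute correlation with the regional map, in (0,1).
#' @slot noiseSd standard deviation of the independent gene noise (> 0).
#' @slot nDonors,probesPerGene probe-level replication structure.
#' @slot seed integer RNG seed.
#' @export
setClass("GeneMatrixSpec",
  representation(nRegions = "integer", nGenes = "integer",
                 nPlantedPos = "integer", nPlantedNeg = "integer",
                 plantedR = "numeric", noiseSd = "numeric",
                 nDonors = "integer", probesPerGene = "integer",
                 seed = "integer"))

setValidity("GeneMatrixSpec", function(object) {
  if (object@nPlantedPos + object@nPlantedNeg >= object@nGenes)
    return("invalid 'nPlantedPos'/'nPlantedNeg': planted genes must number fewer than nGenes")
  if (object@plantedR <= 0 || object@plantedR >= 1)
    return("invalid 'plantedR': must lie strictly between 0 and 1")
  if (object@noiseSd <= 0) return("invalid 'noiseSd': must be > 0")
  TRUE
})

#' @rdname GeneMatrixSpec-class
#' @param nRegions,nGenes,nPlantedPos,nPlantedNeg,plantedR,noiseSd,nDonors,probesPerGene,seed
#'   see the corresponding slots.
#' @return a validated \code{GeneMatrixSpec}.
#' @export
geneMatrixSpec <- function(nRegions = 246L, nGenes = 5451L, nPlantedPos = 0L,
                           nPlantedNeg = 0L, plantedR = 0.8, noiseSd = 1,
                           nDonors = 1L, probesPerGene = 1L, seed = 1L) {
  new("GeneMatrixSpec",
      nRegions = .checkCount(nRegions, "nRegions", 3L),
      nGenes = .checkCount(nGenes, "nGenes"),
      nPlantedPos = .checkCount(nPlantedPos, "nPlantedPos", 0L),
      nPlantedNeg = .checkCount(nPlantedNeg, "nPlantedNeg", 0L),
      plantedR = .checkScalar(plantedR, "plantedR"),
      noiseSd = .checkScalar(noiseSd, "noiseSd"),
      nDonors = .checkCount(nDonors, "nDonors"),
      probesPerGene = .checkCount(probesPerGene, "probesPerGene"),
      seed = .checkCount(seed, "seed", 0L))
}

#' Specification of a synthetic two-group rodent SUV cohort
#'
#' Animals-by-regions standardized uptake value (SUV) tables with
#' block-structured inter-regional covariance: \code{blockStructure} is a list
#' of \code{list(regions =, r =)} entries giving, for each covarying block,
#' the member region indices and the common within-block correlation.
#'
#' @slot nPerGroup animals per group (default 12).
#' @slot nRegions regions (default 22).
#' @slot blockStructure list of covarying blocks (may be empty = independence).
#' @slot suvMean,suvSd marginal SUV mean and standard deviation.
#' @slot seed integer RNG seed.
#' @export
setClass("MouseCohortSpec",
  representation(nPerGroup = "integer", nRegions = "integer",
                 blockStructure = "list", suvMean = "numeric",
                 suvSd = "numeric", seed = "integer"))

setValidity("MouseCohortSpec", function(object) {
  for (b in object@blockStructure) {
    if (!is.list(b) || is.null(b$regions) || is.null(b$r))
      return("invalid 'blockStructure': each block needs 'regions' and 'r'")
    if (abs(b$r) >= 1) return("invalid 'blockStructure': |r| must be < 1")
    if (min(b$regions) < 1 || max(b$regions) > object@nRegions)
      return("invalid 'blockStructure': region indices out of range")
  }
  sigma <- .mouseCorrelation(object)
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    return("invalid 'blockStructure': implied correlation matrix is not positive semi-definite")
  if (object@suvSd <= 0) return("invalid 'suvSd': must be > 0")
  TRUE
})

#' @rdname MouseCohortSpec-class
#' @param nPerGroup,nRegions,blockStructure,suvMean,suvSd,seed see the
#'   corresponding slots.
#' @return a validated \code{MouseCohortSpec}.
#' @export
mouseCohortSpec <- function(nPerGroup = 12L, nRegions = 22L,
                            blockStructure = list(), suvMean = 1,
                            suvSd = 0.15, seed = 1L) {
  new("MouseCohortSpec",
      nPerGroup = .checkCount(nPerGroup, "nPerGroup", 2L),
      nRegions = .checkCount(nRegions, "nRegions", 2L),
      blockStructure = blockStructure,
      suvMean = .checkScalar(suvMean, "suvMean"),
      suvSd = .checkScalar(suvSd, "suvSd"),
      seed = .checkCount(seed, "seed", 0L))
}

# correlation matrix implied by a MouseCohortSpec's block structure
.mouseCorrelation <- function(spec) {
  m <- diag(spec@nRegions)
  for (b in spec@blockStructure) {
    idx <- as.integer(b$regions)
    m[idx, idx] <- b$r
    diag(m)[idx] <- 1
  }
  dimnames(m) <- NULL
  m
}

# ---------------------------------------------------------------------------
# ROISampleSet
# ---------------------------------------------------------------------------

#' Per-subject ROI voxel samples
#'
#' Holds, for one subject, a named list mapping ROI labels to numeric vectors
#' of voxel-level tracer uptake values (SUVR or SUV scale).
#'
#' @slot subjectId subject identifier.
#' @slot samples named list of numeric voxel-value vectors, one per ROI.
#' @export
setClass("ROISampleSet",
  representation(subjectId = "character", samples = "list"))

setValidity("ROISampleSet", function(object) {
  if (length(object@subjectId) != 1L) return("'subjectId' must be a single string")
  if (is.null(names(object@samples)) || anyDuplicated(names(object@samples)))
    return("'samples' must be a uniquely named list of ROI vectors")
  if (!all(vapply(object@samples, is.numeric, logical(1L))))
    return("all ROI samples must be numeric vectors")
  TRUE
})

#' @rdname ROISampleSet-class
#' @param subjectId subject identifier.
#' @param samples named list of numeric voxel-value vectors.
#' @return an \code{ROISampleSet}.
#' @export
ROISampleSet <- function(subjectId, samples)
  new("ROISampleSet", subjectId = as.character(subjectId), samples = samples)

# ---------------------------------------------------------------------------
# DensityEstimate
# ---------------------------------------------------------------------------

#' Kernel density estimate of an ROI uptake distribution
#'
#' A Gaussian-kernel density on a uniform grid, floored at \code{epsilon} and
#' renormalized to unit trapezoidal integral.
#'
#' @slot grid ascending, uniformly spaced evaluation points.
#' @slot density nonnegative density values (same length as \code{grid}).
#' @slot bandwidth kernel bandwidth used (> 0).
#' @slot nSamples number of samples the estimate was computed from.
#' @slot epsilon density floor applied before renormalization.
#' @export
setClass("DensityEstimate",
  representation(grid = "numeric", density = "numeric", bandwidth = "numeric",
                 nSamples = "integer", epsilon = "numeric"))

setValidity("DensityEstimate", function(object) {
  n <- length(object@grid)
  if (length(object@density) != n)
    return("'grid' and 'density' must have equal length")
  if (n >= 2L) {
    dx <- diff(object@grid)
    if (any(dx <= 0)) return("'grid' must be strictly ascending")
    if (diff(range(dx)) > 1e-8 * mean(dx)) return("'grid' must be uniformly spaced")
    if (abs(trapz(object@grid, object@density) - 1) > 1e-3)
      return("'density' must integrate to 1 (trapezoidal) within 1e-3")
  }
  if (any(object@density < 0)) return("'density' must be nonnegative")
  if (object@bandwidth <= 0) return("'bandwidth' must be > 0")
  TRUE
})

# ---------------------------------------------------------------------------
# SimilarityMatrix
# ---------------------------------------------------------------------------

#' Symmetric Kullback-Leibler similarity connectome
#'
#' Square matrix of pairwise Kullback-Leibler similarities
#' \eqn{KLS(P,Q) = \exp(-D_{KL}(P,Q))} between ROI uptake densities, with unit
#' diagonal and off-diagonal entries in (0, 1]. No thresholding is applied.
#'
#' @slot labels ROI identifiers (length N).
#' @slot values N-by-N similarity matrix.
#' @slot meta list recording bandwidth method, grid size and epsilon.
#' @export
setClass("SimilarityMatrix",
  representation(labels = "character", values = "matrix", meta = "list"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@labels)
  if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
    return("'values' must be a numeric N x N matrix matching 'labels'")
  if (max(abs(v - t(v))) > 1e-12) return("'values' must be symmetric within 1e-12")
  if (any(diag(v) != 1)) return("diagonal must be exactly 1")
  off <- v[upper.tri(v)]
  if (length(off) && (any(off <= 0) || any(off > 1)))
    return("off-diagonal similarities must lie in (0, 1]")
  TRUE
})

#' @rdname SimilarityMatrix-class
#' @param labels ROI identifiers.
#' @param values square numeric similarity matrix.
#' @param meta list of estimation metadata.
#' @return a \code{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(labels, values, meta = list()) {
  dimnames(values) <- list(labels, labels)
  new("SimilarityMatrix", labels = as.character(labels), values = values,
      meta = meta)
}

# ---------------------------------------------------------------------------
# GroupDifferenceMap
# ---------------------------------------------------------------------------

#' Covariate-adjusted group-difference map of nodal strength
#'
#' Per-ROI t-values (case minus control), two-sided p-values and
#' Benjamini-Hochberg q-values from linear models of nodal connectivity
#' strength on group plus covariates.
#'
#' @slot labels ROI identifiers.
#' @slot tValue,p,q per-ROI statistics.
#' @slot covariates names of adjustment covariates.
#' @slot alpha FDR threshold used to flag significant ROIs.
#' @slot significant labels of ROIs with q below \code{alpha}.
#' @export
setClass("GroupDifferenceMap",
  representation(labels = "character", tValue = "numeric", p = "numeric",
                 q = "numeric", covariates = "character", alpha = "numeric",
                 significant = "character"))

setValidity("GroupDifferenceMap", function(object) {
  n <- length(object@labels)
  if (length(object@tValue) != n || length(object@p) != n || length(object@q) != n)
    return("'tValue', 'p' and 'q' must match 'labels' in length")
  if (any(!is.finite(object@tValue))) return("t-values must be finite")
  if (any(object@q < object@p - 1e-12)) return("q-values must be >= p-values")
  TRUE
})

# ---------------------------------------------------------------------------
# PLSResult
# ---------------------------------------------------------------------------

#' Partial least squares imaging-transcriptomics result
#'
#' First-component PLS regression of a regional response map on a
#' regions-by-genes expression matrix: regional component scores, per-gene
#' weights (and loadings), bootstrap z-scores and the permutation p-value of
#' the score-response correlation. Sign convention: the correlation between
#' the component scores and the response is nonnegative.
#'
#' @slot regions,genes row/column labels.
#' @slot scores regional component-1 scores.
#' @slot weights,loadings per-gene component-1 weights and loadings.
#' @slot geneZ bootstrap z-scores of the weights (empty until computed).
#' @slot componentR Pearson correlation of scores with the response.
#' @slot componentP permutation p-value (NA until computed).
#' @slot nPerm,nBoot,seed inference bookkeeping.
#' @export
setClass("PLSResult",
  representation(regions = "character", genes = "character",
                 scores = "numeric", weights = "numeric", loadings = "numeric",
                 geneZ = "numeric", componentR = "numeric",
                 componentP = "numeric", nPerm = "integer", nBoot = "integer",
                 seed = "integer"))

setValidity("PLSResult", function(object) {
  if (length(object@scores) != length(object@regions))
    return("'scores' must match 'regions' in length")
  if (length(object@weights) != length(object@genes))
    return("'weights' must match 'genes' in length")
  if (length(object@componentR) == 1L && is.finite(object@componentR) &&
      object@componentR < -1e-12)
    return("sign convention violated: cor(scores, response) must be >= 0")
  if (length(object@componentP) == 1L && is.finite(object@componentP) &&
      (object@componentP <= 0 || object@componentP > 1))
    return("'componentP' must lie in (0, 1]")
  TRUE
})

# ---------------------------------------------------------------------------
# CovarianceNetwork
# ---------------------------------------------------------------------------

#' Group-level regional covariance network
#'
#' Pearson correlations of per-region z-scored SUV across animals, with
#' per-edge permutation p-values from a random-shift null (each region's
#' values independently permuted across animals) and thresholded variants in
#' which edges failing \code{p < alpha} are set to zero.
#'
#' @slot group group label.
#' @slot labels region identifiers (length M).
#' @slot rMatrix M-by-M correlation matrix (unit diagonal).
#' @slot edgeP M-by-M permutation p-values, tail matched to the sign of the
#'   observed correlation (positive and negative tails assessed separately;
#'   both tail matrices are kept in \code{meta}).
#' @slot thresholded named list (by alpha) of masked copies of \code{rMatrix}
#'   with zero diagonal.
#' @slot nPerm,seed permutation bookkeeping.
#' @slot meta list with both tail p-matrices and the null model used.
#' @export
setClass("CovarianceNetwork",
  representation(group = "character", labels = "character",
                 rMatrix = "matrix", edgeP = "matrix", thresholded = "list",
                 nPerm = "integer", seed = "integer", meta = "list"))

setValidity("CovarianceNetwork", function(object) {
  m <- length(object@labels)
  r <- object@rMatrix
  if (nrow(r) != m || ncol(r) != m) return("'rMatrix' must be M x M")
  if (max(abs(r - t(r))) > 1e-12) return("'rMatrix' must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-12)) return("'rMatrix' diagonal must be 1")
  if (any(r < -1 - 1e-12 | r > 1 + 1e-12)) return("correlations must lie in [-1, 1]")
  p <- object@edgeP[upper.tri(object@edgeP)]
  if (length(p) && (any(p <= 0) || any(p > 1)))
    return("'edgeP' must lie in (0, 1]")
  for (th in object@thresholded) {
    keep <- th != 0
    if (any(abs(th[keep] - r[keep]) > 1e-12))
      return("thresholded matrices must be masked copies of 'rMatrix'")
  }
  TRUE
})

#' Graph metrics of a thresholded covariance network
#'
#' @slot alpha edge-retention threshold the metrics were computed at.
#' @slot labels region identifiers.
#' @slot density number of surviving edges.
#' @slot degree per-node surviving-edge count.
#' @slot strengthPos,strengthNeg per-node sums of positive / absolute negative
#'   surviving weights.
#' @slot clustering per-node signed weighted clustering coefficient in [-1,1].
#' @slot hubsStrength,hubsDegree top-quartile node sets by total absolute
#'   strength and by degree.
#' @export
setClass("NetworkProperties",
  representation(alpha = "numeric", labels = "character", density = "integer",
                 degree = "integer", strengthPos = "numeric",
                 strengthNeg = "numeric", clustering = "numeric",
                 hubsStrength = "character", hubsDegree = "character"))

setValidity("NetworkProperties", function(object) {
  if (object@density != sum(object@degree) / 2)
    return("'density' must equal sum(degree)/2")
  if (any(object@strengthNeg < 0)) return("'strengthNeg' must be >= 0")
  if (any(object@clustering < -1 - 1e-12 | object@clustering > 1 + 1e-12))
    return("'clustering' must lie in [-1, 1]")
  TRUE
})
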