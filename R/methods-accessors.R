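#' @include AllGenerics.R
NULL

#' @rdname SimilarityMatrix-class
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(m) m@values)

#' @rdname SimilarityMatrix-class
#' @export
setMethod("roiLabels", "SimilarityMatrix", function(object) object@labels)

#' @rdname GroupDifferenceMap-class
#' @export
setMethod("roiLabels", "GroupDifferenceMap", function(object) object@labels)

#' @rdname GroupDifferenceMap-class
#' @export
setMethod("tValues", "GroupDifferenceMap",
          function(object) setNames(object@tValue, object@labels))

#' @rdname GroupDifferenceMap-class
#' @export
setMethod("qValues", "GroupDifferenceMap",
          function(object) setNames(object@q, object@labels))

#' @rdname GroupDifferenceMap-class
#' @export
setMethod("significantRois", "GroupDifferenceMap",
          function(object) object@significant)

#' @rdname PLSResult-class
#' @export
setMethod("geneWeights", "PLSResult",
          function(object) setNames(object@weights, object@genes))

#' @rdname PLSResult-class
#' @export
setMethod("geneZ", "PLSResult",
          function(object) setNames(object@geneZ, object@genes))

#' @rdname PLSResult-class
#' @export
setMethod("componentScores", "PLSResult",
          function(object) setNames(object@scores, object@regions))

#' @rdname CovarianceNetwork-class
#' @export
setMethod("correlationMatrix", "CovarianceNetwork", function(object) object@rMatrix)

#' @rdname CovarianceNetwork-class
#' @export
setMethod("edgePValues", "CovarianceNetwork", function(object) object@edgeP)

#' @rdname CovarianceNetwork-class
#' @export
setMethod("thresholdedMatrix", "CovarianceNetwork", function(object, alpha) {
  key <- as.character(alpha)
  if (!key %in% names(object@thresholded))
    stop("no thresholded variant at alpha = ", alpha,
         "; available: ", paste(names(object@thresholded), collapse = ", "))
  object@thresholded[[key]]
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "ROISampleSet", function(object) {
  nv <- lengths(object@samples)
  cat("ROISampleSet subject '", object@subjectId, "': ",
      length(object@samples), " ROIs, ",
      min(nv), "-", max(nv), " voxels per ROI\n", sep = "")
})

setMethod("show", "DensityEstimate", function(object) {
  cat("DensityEstimate: ", length(object@grid), " grid points on [",
      format(min(object@grid), digits = 4), ", ",
      format(max(object@grid), digits = 4), "], bandwidth ",
      format(object@bandwidth, digits = 4), ", n = ", object@nSamples,
      "\n", sep = "")
})

setMethod("show", "SimilarityMatrix", function(object) {
  off <- upperTri(object@values)
  cat("SimilarityMatrix: ", length(object@labels), " x ",
      length(object@labels), " KLS connectome\n", sep = "")
  cat("  off-diagonal range: [", format(min(off), digits = 4), ", ",
      format(max(off), digits = 4), "]\n", sep = "")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "GroupDifferenceMap", function(object) {
  cat("GroupDifferenceMap: ", length(object@labels),
      " ROIs (t = case - control, covariates: ",
      paste(object@covariates, collapse = ", "), ")\n", sep = "")
  cat("  ", length(object@significant), " ROIs significant at FDR q < ",
      object@alpha, "\n", sep = "")
})

setMethod("show", "PLSResult", function(object) {
  cat("PLSResult: ", length(object@regions), " regions x ",
      length(object@genes), " genes\n", sep = "")
  cat("  component-1 score-response r = ",
      format(object@componentR, digits = 4), sep = "")
  if (length(object@componentP) && is.finite(object@componentP))
    cat(", permutation p = ", format(object@componentP, digits = 4),
        " (", object@nPerm, " permutations)", sep = "")
  cat("\n")
  if (length(object@geneZ))
    cat("  bootstrap z available for ", length(object@geneZ), " genes (",
        object@nBoot, " resamples)\n", sep = "")
})

setMethod("show", "CovarianceNetwork", function(object) {
  cat("CovarianceNetwork '", object@group, "': ", length(object@labels),
      " x ", length(object@labels), " regions, ", object@nPerm,
      " permutations\n", sep = "")
  for (a in names(object@thresholded))
    cat("  p < ", a, ": ", sum(object@thresholded[[a]][upper.tri(object@thresholded[[a]])] != 0),
        " surviving edges\n", sep = "")
})

setMethod("show", "NetworkProperties", function(object) {
  cat("NetworkProperties (alpha = ", object@alpha, "): density ",
      object@density, ", mean degree ",
      format(mean(object@degree), digits = 3), "\n", sep = "")
  cat("  strength hubs: ", paste(object@hubsStrength, collapse = ", "), "\n",
      "  degree hubs:   ", paste(object@hubsDegree, collapse = ", "), "\n",
      sep = "")
})
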