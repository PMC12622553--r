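#' @include AllClasses.R
NULL

#' Symmetric Kullback-Leibler divergence
#'
#' Computes \eqn{D_{KL}(P,Q) = \sum_i P_i \log(P_i/Q_i) + Q_i \log(Q_i/P_i)}
#' (natural logarithm, so the result is in nats) over normalized discrete
#' probability masses. For \code{\linkS4class{DensityEstimate}} inputs the two
#' estimates must share the same evaluation grid; density values are converted
#' to discrete masses (density times grid spacing, renormalized to sum to 1)
#' first.
#'
#' @param P,Q probability mass vectors of equal length, or two
#'   \code{DensityEstimate} objects on a common grid.
#' @return nonnegative divergence in nats; exactly 0 when \code{P == Q}.
#' @examples
#' klDivergenceSym(c(0.5, 0.5), c(0.9, 0.1))  # 0.8789 nats
#' @export
setGeneric("klDivergenceSym", function(P, Q) standardGeneric("klDivergenceSym"))

#' Kullback-Leibler similarity
#'
#' \eqn{KLS(P,Q) = \exp(-D_{KL}(P,Q))}, constraining the symmetric divergence
#' to (0, 1]; equals 1 iff the divergence is 0 and decreases strictly as the
#' distributions separate.
#'
#' @inheritParams klDivergenceSym
#' @return similarity in (0, 1].
#' @examples
#' klSimilarity(c(0.5, 0.5), c(0.9, 0.1))  # exp(-0.8789)
#' @export
setGeneric("klSimilarity", function(P, Q) standardGeneric("klSimilarity"))

#' Nodal connectivity strength
#'
#' Sum of each node's off-diagonal edge weights: the degree to which a region
#' is connected to all other regions of the weighted network.
#'
#' @param m a \code{\linkS4class{SimilarityMatrix}} (or square numeric matrix).
#' @return named numeric vector of per-node strengths.
#' @export
setGeneric("nodalStrength", function(m) standardGeneric("nodalStrength"))

# ---- accessors ------------------------------------------------------------

#' @rdname SimilarityMatrix-class
#' @param object,m a \code{SimilarityMatrix}.
#' @export
setGeneric("similarityValues", function(m) standardGeneric("similarityValues"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))

#' @rdname GroupDifferenceMap-class
#' @param object a \code{GroupDifferenceMap}.
#' @export
setGeneric("tValues", function(object) standardGeneric("tValues"))

#' @rdname GroupDifferenceMap-class
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))

#' @rdname GroupDifferenceMap-class
#' @export
setGeneric("significantRois", function(object) standardGeneric("significantRois"))

#' @rdname PLSResult-class
#' @param object a \code{PLSResult}.
#' @export
setGeneric("geneWeights", function(object) standardGeneric("geneWeights"))

#' @rdname PLSResult-class
#' @export
setGeneric("geneZ", function(object) standardGeneric("geneZ"))

#' @rdname PLSResult-class
#' @export
setGeneric("componentScores", function(object) standardGeneric("componentScores"))

#' @rdname CovarianceNetwork-class
#' @param object a \code{CovarianceNetwork}.
#' @export
setGeneric("correlationMatrix", function(object) standardGeneric("correlationMatrix"))

#' @rdname CovarianceNetwork-class
#' @export
setGeneric("edgePValues", function(object) standardGeneric("edgePValues"))

#' @rdname CovarianceNetwork-class
#' @param alpha retention threshold of the requested variant.
#' @export
setGeneric("thresholdedMatrix", function(object, alpha) standardGeneric("thresholdedMatrix"))
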