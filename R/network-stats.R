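#' @include AllGenerics.R
NULL

#' @rdname nodalStrength
#' @export
setMethod("nodalStrength", "SimilarityMatrix", function(m) {
  validObject(m)
  v <- m@values
  diag(v) <- 0  # excluded before summing so tiny edges are not cancelled
  setNames(rowSums(v), m@labels)
})

#' @rdname nodalStrength
#' @export
setMethod("nodalStrength", "matrix", function(m) {
  stopifnot(nrow(m) == ncol(m))
  diag(m) <- 0
  s <- rowSums(m)
  if (!is.null(rownames(m))) names(s) <- rownames(m)
  s
})

#' Covariate-adjusted case-control comparison of nodal strength
#'
#' Fits, per ROI, an ordinary least squares model
#' \code{strength ~ group + covariates} with group coded 0 = control, 1 = case,
#' so the reported t-value is signed case minus control. Two-sided p-values
#' for the group coefficient are corrected across ROIs with
#' Benjamini-Hochberg FDR.
#'
#' @param strengths subjects-by-ROI numeric matrix of nodal strengths
#'   (rownames = subject ids), or a list of named strength vectors.
#' @param design data.frame with columns \code{subject_id}, \code{group}
#'   (factor with levels control, case — or coercible), and the covariate
#'   columns; row order must match \code{strengths}.
#' @param fdrAlpha FDR threshold used to flag significant ROIs (default 0.05).
#' @param covariates covariate column names adjusted for (default age, sex).
#' @return a \code{\linkS4class{GroupDifferenceMap}}.
#' @export
compareGroups <- function(strengths, design, fdrAlpha = 0.05,
                          covariates = c("age", "sex")) {
  if (is.list(strengths) && !is.data.frame(strengths) && !is.matrix(strengths))
    strengths <- do.call(rbind, strengths)
  strengths <- as.matrix(strengths)
  if (nrow(strengths) != nrow(design))
    stop("'design' rows must match subjects in 'strengths'")
  grp <- design$group
  if (!is.factor(grp)) grp <- factor(grp, levels = c("control", "case"))
  if (nlevels(grp) != 2L || any(table(grp) < 3L))
    stop("need two groups with at least 3 subjects each")
  missing <- setdiff(covariates, names(design))
  if (length(missing))
    stop("covariates not in design: ", paste(missing, collapse = ", "))

  fml <- stats::reformulate(c("groupIndicator", covariates))
  df <- design
  df$groupIndicator <- as.integer(grp == levels(grp)[2L])
  X <- stats::model.matrix(fml, data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design: group and covariates are confounded ",
         "(e.g. a covariate is constant within group)")

  # one shared design matrix, all ROIs fitted at once
  XtXinv <- chol2inv(qr.R(qrX))
  beta <- XtXinv %*% crossprod(X, strengths)
  resid <- strengths - X %*% beta
  dfree <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dfree
  gIdx <- match("groupIndicator", colnames(X))
  se <- sqrt(XtXinv[gIdx, gIdx] * sigma2)
  tval <- beta[gIdx, ] / se
  p <- 2 * stats::pt(abs(tval), df = dfree, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  labels <- colnames(strengths)
  if (is.null(labels)) labels <- sprintf("ROI%03d", seq_len(ncol(strengths)))
  new("GroupDifferenceMap", labels = labels, tValue = as.numeric(tval),
      p = as.numeric(p), q = as.numeric(q),
      covariates = as.character(covariates), alpha = fdrAlpha,
      significant = labels[q < fdrAlpha])
}
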