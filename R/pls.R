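#' @include AllClasses.R
NULL

.zscore <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  mu <- colMeans(m)
  sdv <- sqrt(pmax(colSums(m * m) - n * mu * mu, 0) / (n - 1))
  sdv[sdv == 0] <- 1  # constant columns contribute nothing
  t((t(m) - mu) / sdv)
}

# component-1 NIPALS step for a univariate response on standardized data:
# weights proportional to X'y, normalized to unit length
.pls1Weights <- function(Xs, ys) {
  w <- crossprod(Xs, ys)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("response is orthogonal to every predictor")
  as.numeric(w / nrm)
}

#' Partial least squares regression of a regional map on gene expression
#'
#' Fits PLS with a univariate regional response (NIPALS): predictor columns
#' and response are z-scored, component weights are the normalized covariance
#' direction \eqn{X^\top y / \|X^\top y\|}, scores are \eqn{X w}, and X and y
#' are deflated between components. Only component 1 is reported in the
#' result object (weights, loadings, regional scores and the score-response
#' Pearson correlation); the sign is fixed so that correlation is
#' nonnegative.
#'
#' @param X regions x genes numeric matrix (rownames = regions, colnames =
#'   genes).
#' @param y regional response vector (e.g. the t-value map of a
#'   \code{\linkS4class{GroupDifferenceMap}}), aligned with the rows of X. If
#'   both carry names they are checked for agreement.
#' @param nComponents number of components to extract before reporting
#'   component 1 (default 1).
#' @return a \code{\linkS4class{PLSResult}}.
#' @export
fitPLS <- function(X, y, nComponents = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of 'X' must align with 'y' by region")
  if (!is.null(rownames(X)) && !is.null(names(y)) &&
      !identical(rownames(X), names(y)))
    stop("region labels of 'X' and 'y' disagree")
  if (nrow(X) <= nComponents)
    stop("need more regions than components")
  yOrig <- as.numeric(y)
  Xs <- .zscore(X)
  ys <- as.numeric(scale(yOrig))
  if (!all(is.finite(ys))) stop("'y' must be nonconstant and finite")

  Xd <- Xs; yd <- ys
  w1 <- t1 <- p1 <- NULL
  for (k in seq_len(max(1L, nComponents))) {
    w <- .pls1Weights(Xd, yd)
    tt <- as.numeric(Xd %*% w)
    pp <- as.numeric(crossprod(Xd, tt) / sum(tt^2))
    if (k == 1L) { w1 <- w; t1 <- tt; p1 <- pp }
    qq <- sum(yd * tt) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pp)
    yd <- yd - tt * qq
  }
  r <- stats::cor(t1, ys)
  if (r < 0) { w1 <- -w1; t1 <- -t1; p1 <- -p1; r <- -r }

  genes <- colnames(X); if (is.null(genes)) genes <- sprintf("G%05d", seq_len(ncol(X)))
  regions <- rownames(X); if (is.null(regions)) regions <- sprintf("R%03d", seq_len(nrow(X)))
  new("PLSResult", regions = regions, genes = genes, scores = t1,
      weights = w1, loadings = p1, geneZ = numeric(0L), componentR = r,
      componentP = NA_real_, nPerm = 0L, nBoot = 0L, seed = NA_integer_)
}

#' Permutation test of the PLS component-1 association
#'
#' Permutes the response over regions \code{nPerm} times, refits component 1,
#' and compares the permuted score-response correlations (which are
#' nonnegative under the sign convention) to the observed one:
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (n_{perm} + 1)}. The add-one
#' correction bounds p below by \eqn{1/(n_{perm}+1)}, never 0.
#'
#' @inheritParams fitPLS
#' @param nPerm number of permutations (default 5000; < 100 draws a warning).
#' @param seed RNG seed.
#' @return the \code{\linkS4class{PLSResult}} of the observed fit with
#'   \code{componentP}, \code{nPerm} and \code{seed} filled in.
#' @export
permutationTestComponent <- function(X, y, nPerm = 5000L, seed = 1L) {
  nPerm <- .checkCount(nPerm, "nPerm")
  if (nPerm < 100L) warning("nPerm < 100 gives a very coarse p-value")
  fit <- fitPLS(X, y)
  Xs <- .zscore(as.matrix(X))
  ys <- as.numeric(scale(as.numeric(y)))
  rPerm <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    yp <- sample(ys)
    w <- crossprod(Xs, yp)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) return(0)
    abs(stats::cor(as.numeric(Xs %*% w), yp))
  }, numeric(1L)))
  fit@componentP <- (1 + sum(rPerm >= fit@componentR)) / (nPerm + 1)
  fit@nPerm <- nPerm
  fit@seed <- as.integer(seed)
  fit
}

#' Bootstrap z-scores of PLS gene weights
#'
#' Resamples regions with replacement \code{nBoot} times, refits component-1
#' weights on each resample, aligns each bootstrap weight vector to the
#' original by the sign of their inner product (PLS components have an
#' arbitrary sign), and reports \eqn{z_g = w_g / \mathrm{sd}^*(w_g)} where
#' \eqn{\mathrm{sd}^*} is the bootstrap standard deviation.
#'
#' @inheritParams fitPLS
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return the observed \code{\linkS4class{PLSResult}} with \code{geneZ},
#'   \code{nBoot} and \code{seed} filled in.
#' @export
bootstrapGeneZ <- function(X, y, nBoot = 1000L, seed = 1L) {
  nBoot <- .checkCount(nBoot, "nBoot")
  fit <- fitPLS(X, y)
  X <- as.matrix(X)
  yNum <- as.numeric(y)
  R <- nrow(X)
  W <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(R, R, replace = TRUE)
      Xb <- .zscore(X[idx, , drop = FALSE])
      yb <- yNum[idx]
      sdy <- stats::sd(yb)
      if (sdy == 0) return(rep(NA_real_, ncol(X)))
      yb <- (yb - mean(yb)) / sdy
      w <- crossprod(Xb, yb)
      nrm <- sqrt(sum(w^2))
      if (nrm == 0) return(rep(NA_real_, ncol(X)))
      w <- as.numeric(w / nrm)
      if (sum(w * fit@weights) < 0) w <- -w
      w
    }, numeric(ncol(X)))
  })
  sdW <- apply(W, 1L, stats::sd, na.rm = TRUE)
  z <- fit@weights / sdW
  bad <- !is.finite(z)
  if (any(bad)) {
    warning(sum(bad), " gene(s) had degenerate bootstrap SD; z set to 0")
    z[bad] <- 0
  }
  fit@geneZ <- z
  fit@nBoot <- nBoot
  fit@seed <- as.integer(seed)
  fit
}

#' Select positively and negatively weighted gene sets
#'
#' Thresholds bootstrap z-scores at strict inequalities \code{z > threshold}
#' (PLS+) and \code{z < -threshold} (PLS-); a gene exactly at the threshold
#' belongs to neither set.
#'
#' @param z named numeric vector of bootstrap z-scores (finite).
#' @param zThreshold threshold (default 3).
#' @return list with character vectors \code{plsPlus}, \code{plsMinus} and the
#'   threshold.
#' @examples
#' selectGeneSets(c(g1 = 4, g2 = -5, g3 = 1))
#' @export
selectGeneSets <- function(z, zThreshold = 3) {
  if (any(!is.finite(z))) stop("z-scores must be finite")
  nm <- names(z); if (is.null(nm)) nm <- sprintf("G%05d", seq_along(z))
  list(plsPlus = nm[z > zThreshold], plsMinus = nm[z < -zThreshold],
       zThreshold = zThreshold)
}
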