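#' @include AllGenerics.R
NULL

.bandwidth <- function(samples, method = c("silverman", "sj")) {
  method <- match.arg(method)
  switch(method,
         silverman = stats::bw.nrd0(samples),
         sj = stats::bw.SJ(samples))
}

.checkSamples <- function(samples) {
  if (length(samples) < 10L)
    stop("need at least 10 samples to estimate a density", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("samples must be finite", call. = FALSE)
  if (length(unique(samples)) < 2L)
    stop("degenerate input: samples are constant, density undefined",
         call. = FALSE)
}

#' Kernel density estimate of a voxel uptake distribution
#'
#' Gaussian-kernel density evaluated on a uniform grid (default 2^9 = 512
#' points spanning the sample range extended by three bandwidths), floored at
#' \code{epsilon} and renormalized to unit trapezoidal integral. The
#' bandwidth is selected automatically: Silverman's rule of thumb by default,
#' or the Sheather-Jones plug-in.
#'
#' @param samples numeric vector of at least 10 voxel values with at least two
#'   distinct values.
#' @param nGrid number of grid points; a power of two >= 64 (default 512).
#' @param bandwidthMethod \code{"silverman"} (default) or \code{"sj"}.
#' @param from,to optional grid end points (both or neither); defaults to the
#'   sample range extended by 3 bandwidths.
#' @param epsilon density floor applied before renormalization (default 1e-12),
#'   preventing infinite divergences on effectively disjoint supports.
#' @param bw optional fixed bandwidth overriding \code{bandwidthMethod}.
#' @return a \code{\linkS4class{DensityEstimate}}.
#' @examples
#' d <- estimateDensity(rnorm(500))
#' length(d@grid)  # 512
#' @export
estimateDensity <- function(samples, nGrid = 512L,
                            bandwidthMethod = c("silverman", "sj"),
                            from = NULL, to = NULL, epsilon = 1e-12,
                            bw = NULL) {
  .checkSamples(samples)
  nGrid <- .checkCount(nGrid, "nGrid", 64L)
  if (bitwAnd(nGrid, nGrid - 1L) != 0L)
    stop("'nGrid' must be a power of two")
  if (is.null(bw)) bw <- .bandwidth(samples, bandwidthMethod)
  if (is.null(from)) from <- min(samples) - 3 * bw
  if (is.null(to)) to <- max(samples) + 3 * bw
  d <- stats::density(samples, bw = bw, kernel = "gaussian", n = nGrid,
                      from = from, to = to)
  y <- pmax(d$y, epsilon)
  y <- y / trapz(d$x, y)
  new("DensityEstimate", grid = d$x, density = y, bandwidth = bw,
      nSamples = length(samples), epsilon = epsilon)
}

# density values -> discrete probability masses on the grid
.densityToMass <- function(est) {
  p <- est@density * (est@grid[2L] - est@grid[1L])
  p / sum(p)
}

.klSymMass <- function(p, q) {
  if (length(p) != length(q))
    stop("mass vectors must have equal length")
  if (any(p < 0) || any(q < 0)) stop("masses must be nonnegative")
  p <- pmax(p, 1e-300); q <- pmax(q, 1e-300)
  p <- p / sum(p); q <- q / sum(q)
  lr <- log(p) - log(q)
  sum(p * lr) - sum(q * lr)
}

#' @rdname klDivergenceSym
#' @export
setMethod("klDivergenceSym", signature("numeric", "numeric"),
          function(P, Q) .klSymMass(P, Q))

#' @rdname klDivergenceSym
#' @export
setMethod("klDivergenceSym", signature("DensityEstimate", "DensityEstimate"),
  function(P, Q) {
    if (length(P@grid) != length(Q@grid) ||
        max(abs(P@grid - Q@grid)) > 1e-9 * diff(range(P@grid)))
      stop("density estimates must share the same evaluation grid")
    .klSymMass(.densityToMass(P), .densityToMass(Q))
  })

#' @rdname klSimilarity
#' @export
setMethod("klSimilarity", signature("numeric", "numeric"),
          function(P, Q) exp(-.klSymMass(P, Q)))

#' @rdname klSimilarity
#' @export
setMethod("klSimilarity", signature("DensityEstimate", "DensityEstimate"),
          function(P, Q) exp(-klDivergenceSym(P, Q)))

# KLS between two raw sample vectors: both densities are evaluated on a
# shared uniform grid spanning the union of the sample ranges extended by
# three bandwidths each, then compared as discrete masses.
.klsPair <- function(x, y, bwx, bwy, nGrid, epsilon) {
  lo <- min(min(x) - 3 * bwx, min(y) - 3 * bwy)
  hi <- max(max(x) + 3 * bwx, max(y) + 3 * bwy)
  dx <- stats::density(x, bw = bwx, kernel = "gaussian", n = nGrid,
                       from = lo, to = hi)$y
  dy <- stats::density(y, bw = bwy, kernel = "gaussian", n = nGrid,
                       from = lo, to = hi)$y
  step <- (hi - lo) / (nGrid - 1L)
  p <- pmax(dx, epsilon) * step
  q <- pmax(dy, epsilon) * step
  exp(-.klSymMass(p, q))
}

#' Build a subject-level KLS synaptic density connectome
#'
#' For every pair of ROIs, estimates the two uptake densities on a shared
#' uniform grid (union of the sample ranges, each extended by three
#' bandwidths) and computes the Kullback-Leibler similarity
#' \eqn{\exp(-D_{KL})}. The diagonal is set to exactly 1 (the similarity of a
#' distribution with itself) and no thresholding is applied.
#'
#' @param subject an \code{\linkS4class{ROISampleSet}}.
#' @param nGrid grid size per pair (power of two, default 512).
#' @param bandwidthMethod automatic bandwidth selector per ROI
#'   (\code{"silverman"} or \code{"sj"}).
#' @param epsilon density floor (default 1e-12).
#' @return a \code{\linkS4class{SimilarityMatrix}} with unit diagonal and
#'   off-diagonal entries in (0, 1].
#' @export
buildSimilarityMatrix <- function(subject, nGrid = 512L,
                                  bandwidthMethod = c("silverman", "sj"),
                                  epsilon = 1e-12) {
  stopifnot(is(subject, "ROISampleSet"))
  bandwidthMethod <- match.arg(bandwidthMethod)
  labels <- names(subject@samples)
  N <- length(labels)
  bws <- vapply(seq_len(N), function(i) {
    tryCatch({
      .checkSamples(subject@samples[[i]])
      .bandwidth(subject@samples[[i]], bandwidthMethod)
    }, error = function(e)
      stop("ROI '", labels[i], "': ", conditionMessage(e), call. = FALSE))
  }, numeric(1L))

  values <- diag(nrow = N)
  if (N >= 2L) {
    for (i in seq_len(N - 1L)) {
      xi <- subject@samples[[i]]
      for (j in seq.int(i + 1L, N)) {
        s <- .klsPair(xi, subject@samples[[j]], bws[i], bws[j], nGrid, epsilon)
        values[i, j] <- s
        values[j, i] <- s
      }
    }
  }
  SimilarityMatrix(labels, values,
                   meta = list(bandwidth_method = bandwidthMethod,
                               n_grid = nGrid, epsilon = epsilon,
                               log_base = "e"))
}
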