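#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the Mersenne-Twister stream seeded at \code{seed},
#' restoring the caller's RNG state afterwards so library calls never clobber
#' a user's random stream. All stochastic functions in the package route their
#' randomness through this helper.
#'
#' @param seed integer scalar, or \code{NULL} to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# trapezoidal integral on an (assumed sorted) grid
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# scalar positive-count check with field-named error
.checkCount <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("invalid '%s': must be an integer >= %d", field, min), call. = FALSE)
  as.integer(x)
}

.checkScalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("invalid '%s': must be a finite numeric scalar", field), call. = FALSE)
  as.numeric(x)
}

# upper-triangle (i < j) values of a square matrix
upperTri <- function(m) m[upper.tri(m)]
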