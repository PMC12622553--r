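# Shared fixture builders. Everything is generated in code under fixed seeds.

# tiny human cohort for structural tests
smallCohort <- function(seed = 7L, nRoi = 6L, ...) {
  generateHumanCohort(humanCohortSpec(nCases = 3L, nControls = 3L,
                                      nRoi = nRoi, voxelsPerRoi = 50L,
                                      seed = seed, ...))
}

# hand-rolled CovarianceNetwork wrapper for metric tests: takes a symmetric
# weight matrix (diag 0) and presents it as the thresholded variant at alpha
fakeNetwork <- function(W, alpha = 0.05, labels = NULL) {
  M <- nrow(W)
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(M))
  r <- W
  diag(r) <- 1
  dimnames(r) <- list(labels, labels)
  p <- matrix(ifelse(W != 0, alpha / 2, 1), M, M)
  diag(p) <- 1e-4
  th <- list(W)
  names(th) <- as.character(alpha)
  dimnames(th[[1L]]) <- dimnames(r)
  new("CovarianceNetwork", group = "fake", labels = labels, rMatrix = r,
      edgeP = p, thresholded = th, nPerm = 1L, seed = 1L, meta = list())
}

# independent signed-clustering oracle: explicit loop over all node triples
bruteForceSignedClustering <- function(W) {
  M <- nrow(W)
  sapply(seq_len(M), function(i) {
    num <- 0; den <- 0
    for (j in seq_len(M)) for (k in seq_len(M)) {
      if (j == i || k == i || j == k) next
      num <- num + W[i, j] * W[i, k] * W[j, k]
      den <- den + abs(W[i, j] * W[i, k])
    }
    if (den == 0) 0 else num / den
  })
}

# independent KLS oracle for two sample vectors: re-evaluates the defining
# formulas (shared grid, floored densities, discrete masses, symmetric KL)
# without calling any package internals
oracleKLS <- function(x, y, nGrid = 512L, epsilon = 1e-12) {
  bwx <- bw.nrd0(x); bwy <- bw.nrd0(y)
  lo <- min(min(x) - 3 * bwx, min(y) - 3 * bwy)
  hi <- max(max(x) + 3 * bwx, max(y) + 3 * bwy)
  dx <- density(x, bw = bwx, n = nGrid, from = lo, to = hi)$y
  dy <- density(y, bw = bwy, n = nGrid, from = lo, to = hi)$y
  step <- (hi - lo) / (nGrid - 1)
  p <- pmax(dx, epsilon) * step; p <- p / sum(p)
  q <- pmax(dy, epsilon) * step; q <- q / sum(q)
  D <- sum(p * log(p / q)) + sum(q * log(q / p))
  exp(-D)
}
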