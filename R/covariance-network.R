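#' @include AllGenerics.R
NULL

.checkSuvTable <- function(tab, minAnimals = 4L) {
  tab <- as.matrix(tab)
  if (!is.numeric(tab) || anyNA(tab)) stop("SUV table must be numeric with no missing values")
  if (nrow(tab) < minAnimals)
    stop("need at least ", minAnimals, " animals")
  sdv <- apply(tab, 2L, stats::sd)
  if (any(sdv == 0)) {
    bad <- colnames(tab)[sdv == 0]
    if (is.null(bad)) bad <- which(sdv == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  tab
}

#' Group-level covariance network with a random-shift permutation null
#'
#' Z-scores each region's SUV across animals, computes all pairwise Pearson
#' correlations, and assesses per-edge significance against a random-shift
#' null built by independently permuting each region's values across animals
#' (destroying the covariance structure while preserving marginals) and
#' recomputing the correlations \code{nPerm} times. The retained per-edge p
#' compares the empirical correlation to the null magnitude,
#' \eqn{p = (1 + \#\{|r_{null}| \ge |r_{obs}|\})/(n_{perm}+1)}, so it is
#' calibrated two-sided; the positive- and negative-tail one-sided p matrices
#' are additionally kept in \code{meta}. The add-one correction makes the
#' minimum attainable p \eqn{1/(n_{perm}+1)}. Thresholded network variants
#' retain edges with \code{p < alpha}.
#'
#' @param groupTable animals x regions numeric SUV matrix (>= 4 animals,
#'   no missing values, no zero-variance region).
#' @param group group label stored on the network.
#' @param nPerm number of permutations (default 10000).
#' @param alphas edge-retention thresholds (default 0.05 and 0.01).
#' @param seed RNG seed.
#' @param nullModel \code{"permute"} (default; independent per-region
#'   permutation) or \code{"circular"} (random circular shift per region).
#' @return a \code{\linkS4class{CovarianceNetwork}}.
#' @export
buildCovarianceNetwork <- function(groupTable, group = "group",
                                   nPerm = 10000L, alphas = c(0.05, 0.01),
                                   seed = 1L,
                                   nullModel = c("permute", "circular")) {
  nullModel <- match.arg(nullModel)
  tab <- .checkSuvTable(groupTable)
  nPerm <- .checkCount(nPerm, "nPerm")
  labels <- colnames(tab)
  if (is.null(labels)) labels <- sprintf("region%02d", seq_len(ncol(tab)))
  M <- ncol(tab); n <- nrow(tab)
  Z <- scale(tab)
  r <- stats::cor(Z)

  geCount <- matrix(0L, M, M)   # null r >= observed r (positive tail)
  leCount <- matrix(0L, M, M)   # null r <= observed r (negative tail)
  magCount <- matrix(0L, M, M)  # |null r| >= |observed r| (two-sided)
  withSeed(seed, {
    P <- Z
    for (b in seq_len(nPerm)) {
      for (j in seq_len(M)) {
        P[, j] <- switch(nullModel,
          permute = Z[sample.int(n), j],
          circular = Z[((seq_len(n) - 1L + sample.int(n, 1L)) %% n) + 1L, j])
      }
      # columns of Z are standardized and permutation preserves that,
      # so the null correlation is a plain cross-product
      rb <- crossprod(P) / (n - 1)
      geCount <- geCount + (rb >= r)
      leCount <- leCount + (rb <= r)
      magCount <- magCount + (abs(rb) >= abs(r))
    }
  })
  pPos <- (geCount + 1) / (nPerm + 1)
  pNeg <- (leCount + 1) / (nPerm + 1)
  edgeP <- (magCount + 1) / (nPerm + 1)
  diag(edgeP) <- 1 / (nPerm + 1)
  dimnames(r) <- dimnames(edgeP) <- list(labels, labels)

  thresholded <- lapply(alphas, function(a) {
    th <- r * (edgeP < a)
    diag(th) <- 0
    th
  })
  names(thresholded) <- as.character(alphas)

  new("CovarianceNetwork", group = as.character(group), labels = labels,
      rMatrix = r, edgeP = edgeP, thresholded = thresholded,
      nPerm = nPerm, seed = as.integer(seed),
      meta = list(pPositiveTail = pPos, pNegativeTail = pNeg,
                  nullModel = nullModel))
}

# signed weighted clustering (Costantini-Perugini): for node i,
#   C_i = sum_{j != k} w_ij w_ik w_jk / sum_{j != k} |w_ij w_ik|
# reduces to the ordinary weighted clustering when all weights are positive
# and equals 1 on complete positive unit-weight graphs.
.signedClustering <- function(W) {
  M <- nrow(W)
  vapply(seq_len(M), function(i) {
    wi <- W[i, ]; wi[i] <- 0
    num <- as.numeric(t(wi) %*% W %*% wi) - sum(wi^2 * diag(W))
    outer <- abs(wi) %o% abs(wi)
    den <- sum(outer) - sum(diag(outer))
    if (den == 0) 0 else num / den
  }, numeric(1L))
}

#' Graph metrics of a thresholded covariance network
#'
#' Computes, on the thresholded variant at \code{alpha}: network density
#' (number of surviving edges), per-node degree, positive and absolute
#' negative strength, the signed weighted clustering coefficient (triangle
#' weights multiply, respecting sign, normalized by the total absolute weight
#' of open triples), and top-quartile hub sets by total absolute strength and
#' by degree (nodes at or above the 75th percentile, linear interpolation;
#' ties all included).
#'
#' @param net a \code{\linkS4class{CovarianceNetwork}}.
#' @param alpha which thresholded variant to analyse (must exist on the
#'   network).
#' @return a \code{\linkS4class{NetworkProperties}}; an empty thresholded
#'   network yields all-zero metrics with a warning.
#' @export
networkProperties <- function(net, alpha) {
  stopifnot(is(net, "CovarianceNetwork"))
  W <- thresholdedMatrix(net, alpha)
  A <- (W != 0) * 1L
  degree <- as.integer(rowSums(A))
  density <- as.integer(sum(A) / 2L)
  if (density == 0L)
    warning("thresholded network at alpha = ", alpha, " has no edges")
  strengthPos <- unname(rowSums(W * (W > 0)))
  strengthNeg <- unname(rowSums(-W * (W < 0)))
  clustering <- .signedClustering(W)
  total <- strengthPos + strengthNeg
  hubS <- net@labels[total >= stats::quantile(total, 0.75) & total > 0]
  hubD <- net@labels[degree >= stats::quantile(degree, 0.75) & degree > 0]
  new("NetworkProperties", alpha = as.numeric(alpha), labels = net@labels,
      density = density, degree = degree, strengthPos = strengthPos,
      strengthNeg = strengthNeg, clustering = clustering,
      hubsStrength = hubS, hubsDegree = hubD)
}

#' Kolmogorov-Smirnov comparison of two networks' edge-weight distributions
#'
#' Two-sample KS test on the upper-triangle edge weights of two networks on
#' the same region set (unthresholded correlations by default, or a
#' thresholded variant's surviving weights).
#'
#' @param netA,netB \code{\linkS4class{CovarianceNetwork}} objects with
#'   identical region labels.
#' @param alpha optional: compare weights of the thresholded variant instead
#'   of the full correlation matrices.
#' @return list with \code{statistic} (in [0,1]) and \code{p}.
#' @export
compareEdgeDistributions <- function(netA, netB, alpha = NULL) {
  stopifnot(is(netA, "CovarianceNetwork"), is(netB, "CovarianceNetwork"))
  if (!identical(netA@labels, netB@labels))
    stop("networks are defined on different region sets")
  getW <- function(net) {
    if (is.null(alpha)) upperTri(net@rMatrix)
    else upperTri(thresholdedMatrix(net, alpha))
  }
  ks <- suppressWarnings(stats::ks.test(getW(netA), getW(netB)))
  list(statistic = unname(ks$statistic), p = ks$p.value)
}

#' Per-edge permutation test of group differences in covariance
#'
#' Tests each edge's between-group correlation difference by randomly
#' reassigning animals to groups (preserving group sizes) \code{nPerm} times
#' and comparing the absolute observed difference to the null distribution
#' (two-sided, add-one corrected, uncorrected across edges; an FDR-adjusted
#' matrix is attached as an attribute).
#'
#' @param groupA,groupB animals x regions SUV matrices sharing region labels.
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param statistic \code{"r"} (plain correlation difference, default) or
#'   \code{"fisher"} (difference of Fisher z-transformed correlations).
#' @return symmetric matrix of two-sided per-edge p-values with attributes
#'   \code{"observedDiff"} (correlation difference A minus B) and
#'   \code{"qValues"} (BH-adjusted upper-triangle p-values, symmetrized).
#' @export
compareEdgesBetweenGroups <- function(groupA, groupB, nPerm = 10000L,
                                      seed = 1L,
                                      statistic = c("r", "fisher")) {
  statistic <- match.arg(statistic)
  A <- as.matrix(groupA); B <- as.matrix(groupB)
  if (!is.null(colnames(A)) && !is.null(colnames(B)) &&
      !identical(colnames(A), colnames(B)))
    stop("groups must share the same region set")
  if (ncol(A) != ncol(B)) stop("groups must share the same region set")
  if (nrow(A) < 4L || nrow(B) < 4L)
    warning("group sizes below 4 give unstable correlation estimates")
  nPerm <- .checkCount(nPerm, "nPerm")

  stat <- function(x) if (statistic == "fisher") atanh(pmin(pmax(x, -1 + 1e-12), 1 - 1e-12)) else x
  obs <- stat(stats::cor(A)) - stat(stats::cor(B))
  pooled <- rbind(A, B)
  nA <- nrow(A); nTot <- nrow(pooled)
  count <- matrix(0L, ncol(A), ncol(A))
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      idx <- sample.int(nTot, nA)
      d <- stat(stats::cor(pooled[idx, , drop = FALSE])) -
        stat(stats::cor(pooled[-idx, , drop = FALSE]))
      count <- count + (abs(d) >= abs(obs))
    }
  })
  p <- (count + 1) / (nPerm + 1)
  diag(p) <- 1
  dimnames(p) <- dimnames(stats::cor(A))
  q <- p
  q[upper.tri(q)] <- stats::p.adjust(p[upper.tri(p)], "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  attr(p, "observedDiff") <- stats::cor(A) - stats::cor(B)
  attr(p, "qValues") <- q
  p
}
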