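#' @include utils.R
NULL

.checkProbeTable <- function(t) {
  need <- c("probe_id", "gene_symbol", "donor_id", "region_id", "intensity")
  missing <- setdiff(need, names(t))
  if (length(missing))
    stop("probe table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(t[c("probe_id", "donor_id", "region_id")]))
    stop("duplicate (probe, donor, region) measurements in probe table")
  if (any(!is.finite(t$intensity))) stop("intensities must be finite")
  invisible(t)
}

#' Intensity-based probe filtering
#'
#' Removes a probe only if its intensity is below \code{factor} times the
#' background level in \emph{all} of its measurements (strict "less than", so
#' a probe sitting exactly at the threshold everywhere is kept).
#'
#' @param probeTable long data.frame with columns probe_id, gene_symbol,
#'   donor_id, region_id, intensity, background.
#' @param factor multiple of background a probe must reach in at least one
#'   sample to be kept (default 1.5, i.e. 50\% above background).
#' @return the filtered probe table.
#' @export
filterProbesIntensity <- function(probeTable, factor = 1.5) {
  .checkProbeTable(probeTable)
  if (is.null(probeTable$background))
    stop("probe table lacks a 'background' column")
  below <- probeTable$intensity < factor * probeTable$background
  allBelow <- tapply(below, probeTable$probe_id, all)
  drop <- names(allBelow)[allBelow]
  probeTable[!probeTable$probe_id %in% drop, , drop = FALSE]
}

#' Differential-stability probe collapse
#'
#' For every probe, differential stability is the mean over donor pairs of the
#' Spearman correlation between the probe's regional expression profiles in
#' the two donors (computed over regions measured in both). For each gene the
#' probe with the highest differential stability is retained; exact ties break
#' to the lexicographically smallest probe id. Probes measurable in fewer
#' than two donors get no score, and a gene with no scorable probe is dropped
#' with a warning.
#'
#' @param probeTable long data.frame (see \code{\link{filterProbesIntensity}}).
#' @return the probe table restricted to the winning probe per gene, with a
#'   \code{"stability"} attribute (data.frame gene_symbol, probe_id, ds).
#' @export
collapseProbesDS <- function(probeTable) {
  .checkProbeTable(probeTable)
  if (length(unique(probeTable$donor_id)) < 2L)
    stop("differential stability needs at least 2 donors")

  probeDS <- function(sub) {
    wide <- tapply(sub$intensity, list(sub$region_id, sub$donor_id), mean)
    donors <- colnames(wide)
    if (length(donors) < 2L) return(NA_real_)
    cors <- c()
    for (a in seq_len(length(donors) - 1L))
      for (b in seq.int(a + 1L, length(donors))) {
        ok <- is.finite(wide[, a]) & is.finite(wide[, b])
        if (sum(ok) >= 2L)
          cors <- c(cors, stats::cor(wide[ok, a], wide[ok, b],
                                     method = "spearman"))
      }
    if (!length(cors)) NA_real_ else mean(cors)
  }

  split <- split(probeTable, probeTable$probe_id)
  ds <- vapply(split, probeDS, numeric(1L))
  gene <- vapply(split, function(s) s$gene_symbol[1L], character(1L))
  tab <- data.frame(probe_id = names(ds), gene_symbol = gene, ds = ds,
                    stringsAsFactors = FALSE)
  # a gene keeps only probes with a score; single-probe genes keep theirs
  keep <- character(0L)
  stab <- list()
  for (g in unique(tab$gene_symbol)) {
    cand <- tab[tab$gene_symbol == g, , drop = FALSE]
    scored <- cand[is.finite(cand$ds), , drop = FALSE]
    if (!nrow(scored)) {
      if (nrow(cand) == 1L) {
        scored <- cand  # lone probe retained even if unscorable
      } else {
        warning("gene '", g, "' dropped: no probe measurable in >= 2 donors")
        next
      }
    }
    best <- scored[order(-ifelse(is.finite(scored$ds), scored$ds, -Inf),
                         scored$probe_id), , drop = FALSE][1L, ]
    keep <- c(keep, best$probe_id)
    stab[[g]] <- best
  }
  out <- probeTable[probeTable$probe_id %in% keep, , drop = FALSE]
  attr(out, "stability") <- do.call(rbind, unname(stab))
  out
}

#' Scaled robust sigmoid normalization
#'
#' Outlier-robust normalization of one gene's expression across regions:
#' \deqn{s_i = 1 / (1 + \exp(-(x_i - \mathrm{median}(x)) / (\mathrm{IQR}(x)/1.35)))}
#' followed by min-max rescaling to [0, 1]. The constant 1.35 makes the IQR
#' a consistent scale estimate under normality.
#'
#' @param x numeric vector (one gene across regions) with positive IQR.
#' @param rescale min-max rescale to [0,1] after the sigmoid (default TRUE).
#' @return normalized vector of the same length.
#' @examples
#' srsNormalize(c(1, 2, 3, 4, 100))
#' @export
srsNormalize <- function(x, rescale = TRUE) {
  if (any(!is.finite(x))) stop("'x' must be finite")
  iqr <- stats::IQR(x)
  if (iqr == 0)
    stop("degenerate input: IQR is zero, scaled robust sigmoid undefined")
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  if (rescale) s <- (s - min(s)) / (max(s) - min(s))
  s
}

#' Assemble a regions-by-genes expression matrix from a probe table
#'
#' Runs the standard microarray preprocessing chain: intensity filtering,
#' differential-stability probe collapse, per-donor aggregation (mean
#' intensity per region), cross-donor averaging, and per-gene scaled robust
#' sigmoid normalization. SRS is applied exactly once, at the end; the result
#' carries a provenance attribute recording that, since applying the sigmoid
#' twice is not idempotent.
#'
#' @param probeTable long probe-level data.frame.
#' @param intensityFactor background multiple for the intensity filter.
#' @param srs apply scaled robust sigmoid per gene (default TRUE).
#' @return regions x genes numeric matrix with dimnames, attribute
#'   \code{"srsApplied"}.
#' @export
buildExpressionMatrix <- function(probeTable, intensityFactor = 1.5,
                                  srs = TRUE) {
  t1 <- filterProbesIntensity(probeTable, intensityFactor)
  t2 <- collapseProbesDS(t1)
  agg <- stats::aggregate(intensity ~ region_id + gene_symbol, data = t2,
                          FUN = mean)
  mat <- tapply(agg$intensity, list(agg$region_id, agg$gene_symbol), mean)
  if (anyNA(mat))
    stop("expression matrix has missing region/gene cells after collapse")
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  if (srs) mat <- apply(mat, 2L, srsNormalize)
  attr(mat, "srsApplied") <- srs
  mat
}

#' Pearson correlation between one gene's regional profile and a map
#'
#' @param geneExpr numeric vector of one gene's expression across regions.
#' @param map aligned regional response vector (length >= 4).
#' @return list with elements \code{r} and \code{p} (two-sided).
#' @export
geneMapCorrelation <- function(geneExpr, map) {
  if (length(geneExpr) != length(map)) stop("vectors must be aligned")
  if (length(map) < 4L) stop("need at least 4 regions")
  if (sd(geneExpr) == 0 || sd(map) == 0) stop("constant input")
  ct <- stats::cor.test(geneExpr, map, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
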