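#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# TSV dialect: UTF-8, tab delimiter, dot decimal; square matrices carry labels
# in the header row and the first column.
# ---------------------------------------------------------------------------

#' Write a labelled square matrix as TSV
#'
#' @param m numeric matrix with identical row/column labels (a bare matrix
#'   gets generated labels).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m)))
    dimnames(m) <- list(sprintf("R%03d", seq_len(nrow(m))),
                        sprintf("R%03d", seq_len(ncol(m))))
  df <- data.frame(label = rownames(m), format(m, digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labelled square matrix from TSV
#'
#' Expects the dialect written by \code{\link{writeMatrixTSV}}: a header row
#' of labels, a leading label column, tab-separated numeric cells. Duplicate
#' labels, ragged rows and non-numeric cells are parse errors that name the
#' offending line.
#'
#' @param path TSV file.
#' @return numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty matrix file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1L]])
  labels <- cells[[1L]][-1L]
  if (anyDuplicated(labels))
    stop("parse error line 1: duplicated labels (",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), ")")
  if (length(cells) - 1L != length(labels))
    stop("parse error: ", length(cells) - 1L, " data rows for ",
         length(labels), " labels")
  vals <- matrix(NA_real_, length(labels), length(labels))
  rlab <- character(length(labels))
  for (i in seq_along(labels)) {
    row <- cells[[i + 1L]]
    if (length(row) != width)
      stop("parse error line ", i + 1L, ": expected ", width, " fields, got ",
           length(row))
    rlab[i] <- row[1L]
    x <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(x))
      stop("parse error line ", i + 1L, ": non-numeric or missing cell")
    vals[i, ] <- x
  }
  if (anyDuplicated(rlab))
    stop("parse error: duplicated row labels")
  dimnames(vals) <- list(rlab, labels)
  vals
}

#' Write / read per-subject ROI voxel samples as long-format TSV
#'
#' Columns: subject_id, roi_id, voxel_value.
#'
#' @param subjects list of \code{\linkS4class{ROISampleSet}} objects.
#' @param path TSV file.
#' @return \code{path} invisibly (writer); list of \code{ROISampleSet}
#'   (reader).
#' @export
writeROISamplesTSV <- function(subjects, path) {
  if (is(subjects, "ROISampleSet")) subjects <- list(subjects)
  rows <- lapply(subjects, function(s)
    data.frame(subject_id = s@subjectId,
               roi_id = rep(names(s@samples), lengths(s@samples)),
               voxel_value = unlist(s@samples, use.names = FALSE)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeROISamplesTSV
#' @export
readROISamplesTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "roi_id", "voxel_value")
  if (!all(need %in% names(df)))
    stop("ROI sample file needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$voxel_value))) stop("non-finite voxel values in ", path)
  lapply(split(df, df$subject_id), function(sub)
    ROISampleSet(sub$subject_id[1L],
                 lapply(split(sub$voxel_value, sub$roi_id), as.numeric)))
}

#' Read a design table (subject_id, group, age, sex) from TSV
#'
#' @param path TSV file.
#' @return data.frame with \code{group} as a control/case factor.
#' @export
readDesignTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop("design file needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("duplicated subject_id in design")
  lv <- unique(df$group)
  lv <- c(intersect(c("control"), lv), setdiff(lv, "control"))
  df$group <- factor(df$group, levels = lv)
  df
}

#' Read a regions-by-genes expression matrix from TSV
#'
#' Region labels in the first column, gene symbols in the header. Constant
#' gene columns draw a warning and are recorded in the
#' \code{"constantGenes"} attribute for downstream rejection.
#'
#' @param path TSV file.
#' @return numeric matrix, regions x genes.
#' @export
readGeneMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]])) stop("duplicated region labels in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression cells in ", path)
  rownames(m) <- df[[1L]]
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv == 0)) {
    warning("constant gene column(s): ",
            paste(colnames(m)[sdv == 0], collapse = ", "))
    attr(m, "constantGenes") <- colnames(m)[sdv == 0]
  }
  m
}

#' Write an analysis summary (with provenance) as JSON
#'
#' @param x named list of results/parameters.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeJSONSummary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a GroupDifferenceMap as TSV
#'
#' Columns: roi, t, p, q, significant.
#'
#' @param map a \code{\linkS4class{GroupDifferenceMap}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeDifferenceMapTSV <- function(map, path) {
  df <- data.frame(roi = map@labels, t = map@tValue, p = map@p, q = map@q,
                   significant = map@labels %in% map@significant)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
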