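#' Construct a time-course expression matrix
#'
#' The basic container for expression time courses: one row per gene, one
#' column per sampling time (hours after synchronization), log2 scale.
#'
#' @param gene_ids character vector of unique gene/probe-set identifiers.
#' @param times_h strictly increasing numeric sampling times in hours.
#' @param values numeric matrix, `length(gene_ids)` rows and
#'   `length(times_h)` columns, finite log2 expression values.
#'
#' @return An object of class `timecourse_matrix` with fields `gene_ids`,
#'   `times_h` and `values`.
#' @export
timecourse_matrix <- function(gene_ids, times_h, values) {
  gene_ids <- as.character(gene_ids)
  times_h <- as.numeric(times_h)
  values <- as.matrix(values)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(times_h) < 1L) stop("at least one sampling time is required")
  if (is.unsorted(times_h, strictly = TRUE))
    stop("sampling times must be strictly increasing")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(times_h))
    stop("values must be ", length(gene_ids), " x ", length(times_h))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, sprintf("T%g", times_h))
  structure(list(gene_ids = gene_ids, times_h = times_h, values = values),
            class = "timecourse_matrix")
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat("timecourse_matrix:", length(x$gene_ids), "genes x",
      length(x$times_h), "time points (",
      min(x$times_h), "-", max(x$times_h), "h )\n")
  invisible(x)
}

#' Read a time-course expression matrix from TSV
#'
#' Expects a gene-identifier column (the first column) followed by one column
#' per time point whose header encodes the sampling time in hours, e.g.
#' `T06`, `T09`, ..., `T30`. Columns are reordered by ascending time.
#'
#' @param path path to a tab-separated file.
#' @param time_header_pattern regular expression with one capture group that
#'   extracts the hour from a time-column header.
#' @return A [timecourse_matrix()].
#' @export
read_timecourse <- function(path, time_header_pattern = "^T0*([0-9]+(?:\\.[0-9]+)?)$") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a gene-id column plus time columns in ", path)
  headers <- colnames(df)[-1L]
  m <- regmatches(headers, regexec(time_header_pattern, headers, perl = TRUE))
  bad <- vapply(m, length, 1L) < 2L
  if (any(bad))
    stop("malformed time header(s): ", paste(headers[bad], collapse = ", "))
  times <- as.numeric(vapply(m, `[`, "", 2L))
  if (anyNA(times))
    stop("malformed time header(s): ",
         paste(headers[is.na(times)], collapse = ", "))
  for (j in seq_along(headers)) {
    col <- df[[j + 1L]]
    if (!is.numeric(col)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop("non-numeric value at row ", bad_row, ", column '", headers[j], "'")
    }
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(times)
  timecourse_matrix(ids, times[ord], as.matrix(df[, -1L, drop = FALSE])[, ord, drop = FALSE])
}

#' Write a time-course matrix to TSV
#'
#' Inverse of [read_timecourse()]: round-tripping reproduces values to
#' better than 1e-12 relative precision.
#'
#' @param tc a [timecourse_matrix()].
#' @param path output path.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  hdr <- sprintf("T%02g", tc$times_h)
  df <- data.frame(gene_id = tc$gene_ids,
                   format(tc$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", hdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
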