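#' Construct a splicing-event structure annotation
#'
#' Describes the two transcript paths of an alternative-splicing event as
#' lists of genomic intervals. Coordinates are 0-based half-open throughout;
#' intervals are kept in genomic order regardless of strand.
#'
#' @param event_id,gene_id identifiers.
#' @param chrom,strand chromosome name and strand (`"+"` or `"-"`).
#' @param path_inclusion,path_exclusion data.frames with columns
#'   `start`, `end` (0-based half-open, `start < end`), the intervals used by
#'   the inclusion and the exclusion isoform respectively.
#' @param flank_intervals optional data.frame of intervals shared by both
#'   paths (constitutive flanks).
#' @return An object of class `event_annotation`.
#' @export
event_annotation <- function(event_id, gene_id, chrom, strand,
                             path_inclusion, path_exclusion,
                             flank_intervals = NULL) {
  chk <- function(df, what) {
    df <- as.data.frame(df)[, c("start", "end")]
    if (nrow(df) && any(df$start >= df$end))
      stop("invalid interval (start >= end) in ", what, " of ", event_id)
    df[order(df$start, df$end), , drop = FALSE]
  }
  incl <- chk(path_inclusion, "inclusion path")
  excl <- chk(path_exclusion, "exclusion path")
  if (is.null(flank_intervals))
    flank_intervals <- data.frame(start = numeric(), end = numeric())
  flank <- chk(flank_intervals, "flanks")
  if (!(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (identical(interval_keys(incl), interval_keys(excl)))
    stop("inclusion and exclusion paths of ", event_id,
         " are identical; they must differ in at least one interval")
  structure(list(event_id = as.character(event_id),
                 gene_id = as.character(gene_id),
                 chrom = as.character(chrom), strand = strand,
                 path_inclusion = incl, path_exclusion = excl,
                 flank_intervals = flank),
            class = "event_annotation")
}

interval_keys <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$start, df$end, sep = "-"))
}

#' Read splicing-event annotations from TSV
#'
#' One interval per row with header columns `event_id`, `gene_id`, `chrom`,
#' `strand`, `path` (one of `incl`, `excl`, `flank`), `start`, `end`
#' (0-based half-open).
#'
#' @param path input TSV path.
#' @return Named list of [event_annotation()] objects.
#' @export
read_event_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "gene_id", "chrom", "strand", "path", "start", "end")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- !df$path %in% c("incl", "excl", "flank")
  if (any(bad)) stop("unknown path value '", df$path[bad][1L], "'")
  out <- lapply(split(df, df$event_id), function(e) {
    event_annotation(e$event_id[1L], e$gene_id[1L], e$chrom[1L], e$strand[1L],
                     e[e$path == "incl", c("start", "end")],
                     e[e$path == "excl", c("start", "end")],
                     e[e$path == "flank", c("start", "end")])
  })
  out[unique(df$event_id)]
}

#' Write splicing-event results as BED6
#'
#' One line per event: `chrom start end name score strand` where
#' `name = gene:event_id:type` and
#' `score = round(1000 * min(1, |dPSI_max|))` with `dPSI_max` the largest
#' absolute per-comparison delta-PSI. Events without a genomic interval are
#' skipped with a warning. An empty result list produces a file holding only
#' the header comment.
#'
#' @param results list of splicing-event results (see
#'   [splicing_event_result()]) or the data.frame from
#'   [intersect_recurrent()] carrying `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `event_id`, `event_type` and per-comparison `dpsi` values.
#' @param path output BED path.
#' @export
write_events_bed <- function(results, path) {
  if (is.data.frame(results))
    results <- lapply(seq_len(nrow(results)), function(i) as.list(results[i, ]))
  lines <- "# BED6: chrom start end gene:event:type score strand"
  for (r in results) {
    if (is.null(r$chrom) || is.na(r$chrom) ||
        is.null(r$start) || is.na(r$start)) {
      warning("event ", r$event_id, " has no genomic interval; skipped")
      next
    }
    dpsi <- unlist(r[grepl("^dpsi", names(r))], use.names = FALSE)
    if (!length(dpsi) && !is.null(r$delta_psi)) dpsi <- r$delta_psi
    score <- round(1000 * min(1, max(abs(dpsi))))
    lines <- c(lines, paste(r$chrom, r$start, r$end,
                            paste(r$gene_id, r$event_id, r$event_type,
                                  sep = ":"),
                            score, r$strand, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR CT table from TSV
#'
#' Header columns: `sample_id`, `gene_id`, `replicate`, `ct`, plus optional
#' `time_h` and `condition` carried through.
#'
#' @param path input TSV path.
#' @return data.frame of CT measurements.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "ct")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$ct)) stop("ct column must be numeric")
  df
}

#' Write a qPCR CT table to TSV
#' @param ct_table data.frame as returned by [read_ct_table()].
#' @param path output path.
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.table(ct_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
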