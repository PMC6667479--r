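#' Construct a probe-level event quantification
#'
#' Holds the log2 probe intensities of the inclusion and exclusion paths of
#' one splicing event across samples, plus the derived per-sample PSI.
#'
#' @param event_id event identifier.
#' @param sample_ids sample names (columns of the probe matrices).
#' @param times_h sampling time of each sample, hours.
#' @param incl_probes,excl_probes numeric matrices (probes x samples, log2
#'   intensity); at least one probe per path; `-Inf` encodes a path
#'   abundance of exactly zero on the linear scale.
#' @return An object of class `event_quantification` with the fields above
#'   plus `psi_per_sample`.
#' @export
event_quantification <- function(event_id, sample_ids, times_h,
                                 incl_probes, excl_probes) {
  incl_probes <- rbind(incl_probes); excl_probes <- rbind(excl_probes)
  if (ncol(incl_probes) != length(sample_ids) ||
      ncol(excl_probes) != length(sample_ids))
    stop("probe matrices must share the sample columns")
  if (nrow(incl_probes) < 1L || nrow(excl_probes) < 1L)
    stop("need at least one probe per path")
  colnames(incl_probes) <- colnames(excl_probes) <- sample_ids
  psi <- vapply(seq_along(sample_ids), function(j)
    estimate_psi(incl_probes[, j], excl_probes[, j]), numeric(1))
  structure(list(event_id = as.character(event_id),
                 sample_ids = as.character(sample_ids),
                 times_h = as.numeric(times_h),
                 incl_probes = incl_probes, excl_probes = excl_probes,
                 psi_per_sample = stats::setNames(psi, sample_ids)),
            class = "event_quantification")
}

#' Estimate PSI from one sample's probe intensities
#'
#' The percent spliced-in index is the ratio between the signal of the
#' inclusion path and the total path signal, `PSI = I / (I + E)`, where `I`
#' and `E` are the medians of the linear-scale (`2^x`) probe intensities of
#' the inclusion and exclusion path. Median summarization makes the estimate
#' robust to single aberrant probes.
#'
#' @param incl_probes,excl_probes numeric vectors of log2 probe intensities
#'   (one value per probe) for the two paths.
#' @return PSI in [0, 1].
#' @export
estimate_psi <- function(incl_probes, excl_probes) {
  if (!length(incl_probes) || !length(excl_probes))
    stop("need at least one probe per path")
  I <- stats::median(2^incl_probes)
  E <- stats::median(2^excl_probes)
  if (I + E == 0) stop("undefined PSI: total path signal is zero")
  I / (I + E)
}

#' Plan binned pairwise comparisons over a time course
#'
#' After removing `excluded` times, consecutive pairs of the remaining
#' (sorted) time points form bins and consecutive bins form comparisons.
#' With the default 6-30 h / 3 h grid and the 18 h time point excluded this
#' yields bins (6,9), (12,15), (21,24), (27,30) and three comparisons.
#'
#' @param times_h sampling times.
#' @param excluded times to drop before binning (e.g. 18).
#' @return An object of class `comparison_plan`: list with `bins` (list of
#'   length-2 time vectors), `comparisons` (list of consecutive bin-index
#'   pairs) and `excluded_times`.
#' @export
plan_comparisons <- function(times_h, excluded = numeric()) {
  kept <- sort(setdiff(times_h, excluded))
  if (length(kept) < 4L)
    stop("need at least 4 time points after exclusion")
  if (length(kept) %% 2L != 0L)
    stop("odd number of time points (", length(kept),
         ") after exclusion; exclude one more time point (e.g. ",
         kept[length(kept)], " h)")
  nb <- length(kept) / 2L
  bins <- lapply(seq_len(nb), function(i) kept[c(2 * i - 1, 2 * i)])
  comparisons <- lapply(seq_len(nb - 1L), function(i) c(i, i + 1L))
  structure(list(bins = bins, comparisons = comparisons,
                 excluded_times = sort(excluded)),
            class = "comparison_plan")
}

#' @export
print.comparison_plan <- function(x, ...) {
  cat("comparison_plan:", length(x$bins), "bins,",
      length(x$comparisons), "comparisons")
  if (length(x$excluded_times))
    cat("; excluded:", paste(x$excluded_times, collapse = ", "), "h")
  cat("\n")
  invisible(x)
}

#' Test one event for differential splicing between two bins
#'
#' The delta-PSI is the difference of mean per-sample PSI between the bins
#' (`bin_b` minus `bin_a`). The p-value comes from an F-test of the
#' path-by-bin interaction in the linear model
#' `log2 intensity ~ probe + sample + path:bin`
#' fitted over all probes of both paths across the four samples of the two
#' bins. The probe blocking factor absorbs fixed per-probe affinities (and,
#' nested within it, the path main effect), sample effects absorb overall
#' abundance changes, and the one-degree-of-freedom interaction captures a
#' shift of the isoform balance between bins.
#'
#' @param quant an [event_quantification()].
#' @param bin_a,bin_b numeric vectors of sampling times (typically 2 each)
#'   selecting the samples of the two bins; all must be present in `quant`.
#' @return list with `delta_psi` (in [-1, 1]) and `p_value` (in (0, 1]).
#' @export
test_event <- function(quant, bin_a, bin_b) {
  stopifnot(inherits(quant, "event_quantification"))
  idx <- function(ts) {
    i <- match(ts, quant$times_h)
    if (anyNA(i)) stop("sample at ", ts[which(is.na(i))[1L]],
                       " h missing from quantification")
    i
  }
  ia <- idx(bin_a); ib <- idx(bin_b)
  delta_psi <- mean(quant$psi_per_sample[ib]) -
    mean(quant$psi_per_sample[ia])

  cols <- c(ia, ib)
  bin <- rep(c(0, 1), c(length(ia), length(ib)))
  long <- function(m, path_code) {
    data.frame(y = as.vector(m[, cols, drop = FALSE]),
               sample = factor(rep(cols, each = nrow(m))),
               probe = paste0(path_code, seq_len(nrow(m))),
               path = as.numeric(path_code == "I"),
               bin = rep(bin, each = nrow(m)))
  }
  d <- rbind(long(quant$incl_probes, "I"), long(quant$excl_probes, "E"))
  d$probe <- factor(d$probe)
  if (any(!is.finite(d$y)))
    d$y[!is.finite(d$y)] <- min(d$y[is.finite(d$y)], 0) - 10
  d$int <- d$path * d$bin
  fit_red <- stats::lm(y ~ probe + sample, data = d)
  fit_full <- stats::lm(y ~ probe + sample + int, data = d)
  ss_red <- sum(stats::residuals(fit_red)^2)
  ss_full <- sum(stats::residuals(fit_full)^2)
  df_res <- fit_full$df.residual
  if (df_res < 1L) stop("zero residual degrees of freedom")
  ss_int <- ss_red - ss_full
  tol <- 1e-12 * max(sum((d$y - mean(d$y))^2), 1)
  if (ss_int <= tol) {
    p <- 1
  } else if (ss_full <= tol) {
    p <- .Machine$double.xmin
  } else {
    f <- ss_int / (ss_full / df_res)
    p <- max(stats::pf(f, 1, df_res, lower.tail = FALSE),
             .Machine$double.xmin)
  }
  list(delta_psi = delta_psi, p_value = min(p, 1))
}

#' Run all planned comparisons for a set of events
#'
#' Convenience wrapper applying [test_event()] to every event and every
#' comparison of a [plan_comparisons()] plan.
#'
#' @param quants named list of [event_quantification()] objects.
#' @param plan a `comparison_plan`.
#' @return list of data.frames, one per comparison, each with columns
#'   `event_id`, `delta_psi`, `p_value`.
#' @export
run_comparisons <- function(quants, plan) {
  stopifnot(inherits(plan, "comparison_plan"))
  lapply(plan$comparisons, function(cmp) {
    ba <- plan$bins[[cmp[1]]]; bb <- plan$bins[[cmp[2]]]
    res <- lapply(quants, test_event, bin_a = ba, bin_b = bb)
    data.frame(event_id = names(quants),
               delta_psi = vapply(res, `[[`, 0, "delta_psi"),
               p_value = vapply(res, `[[`, 0, "p_value"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Filter per-comparison splicing results
#'
#' Keeps events with `p_value < p_max` (strict) and
#' `|delta_psi| > dpsi_min` (strict); input order is preserved.
#'
#' @param results data.frame with `p_value` and `delta_psi` columns.
#' @param p_max p-value threshold (default 0.01).
#' @param dpsi_min absolute delta-PSI threshold (default 0.1).
#' @return The filtered data.frame.
#' @export
filter_events <- function(results, p_max = 0.01, dpsi_min = 0.1) {
  keep <- results$p_value < p_max & abs(results$delta_psi) > dpsi_min
  results[keep, , drop = FALSE]
}

#' Intersect events recurring across all comparisons
#'
#' Returns the events significant (`p < p_max`) in every comparison at the
#' same identity/coordinates and with `|delta_psi| >= dpsi_min` in at least
#' one comparison, flagged as recurrent. Note the deliberate asymmetry with
#' [filter_events()]: the delta-PSI condition is non-strict here and only
#' required once.
#'
#' @param per_comparison_results list of per-comparison data.frames as from
#'   [run_comparisons()]; all must cover the same events in the same order.
#' @param p_max,dpsi_min thresholds (defaults 0.01 and 0.1).
#' @return data.frame with `event_id`, per-comparison `dpsi_<k>` and
#'   `p_<k>` columns, `dpsi_variance` and `recurrent = TRUE`.
#' @export
intersect_recurrent <- function(per_comparison_results, p_max = 0.01,
                                dpsi_min = 0.1) {
  k <- length(per_comparison_results)
  if (k < 2L) stop("need at least two comparisons")
  ids <- per_comparison_results[[1L]]$event_id
  for (r in per_comparison_results[-1L])
    if (!identical(r$event_id, ids))
      stop("comparisons cover different events; annotation mismatch")
  p_mat <- sapply(per_comparison_results, `[[`, "p_value")
  d_mat <- sapply(per_comparison_results, `[[`, "delta_psi")
  p_mat <- rbind(p_mat); d_mat <- rbind(d_mat)
  keep <- rowSums(p_mat < p_max) == k & rowSums(abs(d_mat) >= dpsi_min) >= 1L
  out <- data.frame(event_id = ids[keep], stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    out[[paste0("dpsi_", j)]] <- d_mat[keep, j]
    out[[paste0("p_", j)]] <- p_mat[keep, j]
  }
  out$dpsi_variance <- apply(d_mat[keep, , drop = FALSE], 1, stats::var)
  out$recurrent <- rep(TRUE, sum(keep))
  out
}

#' Rank events by the variance of their delta-PSI values
#'
#' Descending by the sample variance (n - 1 denominator) of the
#' per-comparison delta-PSI values; ties broken by event id
#' (lexicographic) for determinism. Input row order does not affect the
#' result.
#'
#' @param results data.frame with an `event_id` column and either a
#'   `dpsi_variance` column or `dpsi_*` columns to compute it from.
#' @return The reordered data.frame with a `dpsi_variance` column.
#' @export
rank_by_dpsi_variance <- function(results) {
  if (is.null(results$dpsi_variance)) {
    dcols <- grep("^dpsi_[0-9]+$", colnames(results), value = TRUE)
    if (length(dcols) < 2L)
      stop("need at least two delta-PSI values per event")
    results$dpsi_variance <- apply(results[, dcols, drop = FALSE], 1,
                                   stats::var)
  }
  results[order(-results$dpsi_variance, results$event_id), , drop = FALSE]
}

#' Classify a splicing event from its path structure
#'
#' Compares the interval sets of the inclusion and exclusion paths:
#' * `cassette_exon` — the paths differ by exactly one internal interval
#'   with shared intervals flanking it on both sides;
#' * `intron_retention` — one path's single interval spans the other
#'   path's two intervals plus the gap between them;
#' * `alt_5ss` / `alt_3ss` — one differing interval pair sharing one
#'   boundary, with a shared interval beyond the changed end; the changed
#'   end is mapped to donor/acceptor strand-aware;
#' * `alt_first_exon` / `alt_last_exon` — the divergence involves the
#'   transcript's first/last interval with no shared interval beyond it on
#'   that side;
#' * `complex` — anything else.
#'
#' @param annotation an [event_annotation()].
#' @return character scalar, one of the types above.
#' @export
classify_event <- function(annotation) {
  stopifnot(inherits(annotation, "event_annotation"))
  incl <- annotation$path_inclusion
  excl <- annotation$path_exclusion
  plus <- annotation$strand == "+"
  key <- function(df) paste(df$start, df$end, sep = "-")
  ki <- key(incl); ke <- key(excl)
  shared <- merge(incl, excl)[, c("start", "end")]
  d_i <- incl[!(ki %in% ke), , drop = FALSE]   # intervals unique to incl
  d_e <- excl[!(ke %in% ki), , drop = FALSE]

  spans <- function(one, two) {
    nrow(one) == 1L && nrow(two) == 2L &&
      one$start == min(two$start) && one$end == max(two$end) &&
      max(two$start) > min(two$end)
  }
  if (spans(d_e, d_i) || spans(d_i, d_e)) return("intron_retention")

  shared_left_of <- function(pos) nrow(shared) && any(shared$end <= pos)
  shared_right_of <- function(pos) nrow(shared) && any(shared$start >= pos)

  # one path has a single extra interval, the other none
  if ((nrow(d_i) == 1L && nrow(d_e) == 0L) ||
      (nrow(d_e) == 1L && nrow(d_i) == 0L)) {
    x <- if (nrow(d_i)) d_i else d_e
    left <- shared_left_of(x$start); right <- shared_right_of(x$end)
    if (left && right) return("cassette_exon")
    if (!right) return(if (plus) "alt_last_exon" else "alt_first_exon")
    if (!left) return(if (plus) "alt_first_exon" else "alt_last_exon")
  }

  # single differing interval pair
  if (nrow(d_i) == 1L && nrow(d_e) == 1L) {
    if (d_i$start == d_e$start && d_i$end != d_e$end) {
      # right end changes
      if (shared_right_of(max(d_i$end, d_e$end)))
        return(if (plus) "alt_5ss" else "alt_3ss")
      return(if (plus) "alt_last_exon" else "alt_first_exon")
    }
    if (d_i$end == d_e$end && d_i$start != d_e$start) {
      if (shared_left_of(min(d_i$start, d_e$start)))
        return(if (plus) "alt_3ss" else "alt_5ss")
      return(if (plus) "alt_first_exon" else "alt_last_exon")
    }
    # disjoint terminal swap
    lo <- min(d_i$start, d_e$start); hi <- max(d_i$end, d_e$end)
    if (!shared_right_of(hi))
      return(if (plus) "alt_last_exon" else "alt_first_exon")
    if (!shared_left_of(lo))
      return(if (plus) "alt_first_exon" else "alt_last_exon")
  }
  "complex"
}

#' Build final splicing-event results with annotation
#'
#' Joins recurrent (or per-comparison) statistics with event annotations:
#' adds gene, genomic span (the union of both paths' intervals) and the
#' classified event type, ready for [write_events_bed()].
#'
#' @param stats data.frame with an `event_id` column (e.g. from
#'   [intersect_recurrent()]).
#' @param annotations named list of [event_annotation()] objects.
#' @return `stats` extended with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and `event_type`.
#' @export
splicing_event_result <- function(stats, annotations) {
  ann_row <- function(id) {
    a <- annotations[[id]]
    if (is.null(a))
      return(data.frame(gene_id = NA_character_, chrom = NA_character_,
                        start = NA_real_, end = NA_real_,
                        strand = NA_character_,
                        event_type = NA_character_))
    iv <- rbind(a$path_inclusion, a$path_exclusion)
    data.frame(gene_id = a$gene_id, chrom = a$chrom,
               start = min(iv$start), end = max(iv$end), strand = a$strand,
               event_type = classify_event(a), stringsAsFactors = FALSE)
  }
  cbind(stats, do.call(rbind, lapply(stats$event_id, ann_row)))
}
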