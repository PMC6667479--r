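#' Correlate two gene sets across a time course
#'
#' Pairwise Pearson or Spearman correlation of the series of two row sets of
#' a time-course matrix across its time columns. Spearman uses average ranks
#' for ties. Series with zero variance yield `NA` entries and a warning —
#' never a silent zero.
#'
#' @param matrix a [timecourse_matrix()].
#' @param rows_a,rows_b character vectors of gene ids present in `matrix`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Numeric matrix (`rows_a` x `rows_b`) of correlations with
#'   attribute `method`.
#' @export
correlate_sets <- function(matrix, rows_a, rows_b,
                           method = c("pearson", "spearman")) {
  stopifnot(inherits(matrix, "timecourse_matrix"))
  method <- match.arg(method)
  if (length(matrix$times_h) < 3L) stop("need at least 3 time points")
  miss <- setdiff(c(rows_a, rows_b), matrix$gene_ids)
  if (length(miss)) stop("gene(s) not in matrix: ",
                         paste(miss, collapse = ", "))
  A <- matrix$values[rows_a, , drop = FALSE]
  B <- matrix$values[rows_b, , drop = FALSE]
  flat <- c(rows_a[apply(A, 1, stats::var) == 0],
            rows_b[apply(B, 1, stats::var) == 0])
  if (length(flat))
    warning("zero-variance series, correlations undefined (NA): ",
            paste(unique(flat), collapse = ", "))
  out <- suppressWarnings(stats::cor(t(A), t(B), method = method))
  dimnames(out) <- list(rows_a, rows_b)
  attr(out, "method") <- method
  out
}

#' Spearman correlation between paired per-dataset counts
#'
#' Used to relate the numbers of oscillating genes found in two gene sets
#' (e.g. clock-regulated genes vs splicing factors) across several datasets.
#'
#' @param counts_a,counts_b equal-length numeric vectors (>= 3 datasets).
#' @return Spearman rho.
#' @export
oscillating_count_correlation <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop("count vectors differ in length")
  if (length(counts_a) < 3L) stop("need at least 3 datasets")
  stats::cor(counts_a, counts_b, method = "spearman")
}

#' Relative qPCR quantification by the 2^-ddCT method
#'
#' CT replicates are averaged per sample and gene; then
#' `dCT = CT_target - CT_reference` per sample,
#' `ddCT = dCT - dCT_calibrator` and
#' `relative_expression = 2^-ddCT`. The calibrator is either a sample id
#' (control-relative quantification) or `"mean"`, which calibrates each gene
#' to its mean dCT across the time course (per condition when a `condition`
#' column is present) — the convention used when fitting rhythms to qPCR
#' series.
#'
#' @param ct_table data.frame with columns `sample_id`, `gene_id`, `ct` and
#'   optionally `replicate`, `time_h`, `condition`.
#' @param reference_gene id of the reference gene (must be measured in every
#'   sample).
#' @param calibrator `"mean"` (default) or a sample id present in the table.
#' @return data.frame with one row per sample and target gene: `sample_id`,
#'   `gene_id`, `ct`, `delta_ct`, `delta_delta_ct`, `relative_expression`
#'   (plus `time_h`/`condition` when supplied).
#' @export
quantify_ddct <- function(ct_table, reference_gene, calibrator = "mean") {
  need <- c("sample_id", "gene_id", "ct")
  miss <- setdiff(need, colnames(ct_table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  keep <- intersect(c("sample_id", "time_h", "condition", "gene_id"),
                    colnames(ct_table))
  agg <- stats::aggregate(ct_table["ct"], ct_table[keep], mean)

  ref <- agg[agg$gene_id == reference_gene, ]
  tgt <- agg[agg$gene_id != reference_gene, ]
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  no_ref <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(no_ref))
    stop("reference gene ", reference_gene, " missing in sample(s): ",
         paste(no_ref, collapse = ", "))
  tgt$delta_ct <- tgt$ct - ref_ct[tgt$sample_id]

  grp <- if ("condition" %in% colnames(tgt))
    paste(tgt$gene_id, tgt$condition) else tgt$gene_id
  if (identical(calibrator, "mean")) {
    cal <- stats::ave(tgt$delta_ct, grp)
  } else {
    if (!calibrator %in% tgt$sample_id)
      stop("calibrator sample not found: ", calibrator)
    cal_tab <- tgt[tgt$sample_id == calibrator, ]
    cal <- cal_tab$delta_ct[match(tgt$gene_id, cal_tab$gene_id)]
  }
  tgt$delta_delta_ct <- tgt$delta_ct - cal
  tgt$relative_expression <- 2^(-tgt$delta_delta_ct)
  rownames(tgt) <- NULL
  tgt
}

#' Fit circadian rhythms to qPCR quantifications, with condition contrast
#'
#' Per gene and condition, fits [scan_periods()] to the mean-normalized
#' log2 relative expression (equal to `-ddCT` under mean calibration) over
#' the period grid (default 14-27 h in 0.1 h steps). When exactly two
#' conditions are present the acrophase shift of the second relative to the
#' first (alphabetically, or the order of `conditions`) is reported via
#' [acrophase_shift()]; because acrophases at different periods are not
#' comparable, both series are refit at the first condition's best period
#' for the shift computation. Fits with p >= `alpha` are flagged
#' non-rhythmic.
#'
#' @param quants data.frame from [quantify_ddct()] carrying `time_h` (and
#'   optionally `condition`).
#' @param period_range_h,step_h period grid (defaults 14-27 h by 0.1 h).
#' @param alpha rhythmicity threshold on the fit p-value (default 0.05).
#' @param conditions optional character vector fixing the condition order
#'   (first = reference for the shift).
#' @return list with one entry per gene: `fits` (named list of
#'   `harmonic_fit` per condition), `rhythmic` (named logical),
#'   `acrophase_shift_h` (NA when not computable).
#' @export
fit_qpcr_rhythms <- function(quants, period_range_h = c(14, 27),
                             step_h = 0.1, alpha = 0.05,
                             conditions = NULL) {
  if (is.null(quants$time_h)) stop("quants must carry a time_h column")
  if (is.null(quants$condition)) quants$condition <- "control"
  out <- list()
  for (gene in unique(quants$gene_id)) {
    gq <- quants[quants$gene_id == gene, ]
    conds <- if (is.null(conditions)) sort(unique(gq$condition)) else
      intersect(conditions, unique(gq$condition))
    fits <- list(); series_by_cond <- list()
    for (cond in conds) {
      cq <- gq[gq$condition == cond, ]
      cq <- cq[order(cq$time_h), ]
      if (nrow(cq) < 4L) stop("fewer than 4 time points for ", gene,
                              " / ", cond)
      series_by_cond[[cond]] <- list(y = log2(cq$relative_expression),
                                     t = cq$time_h)
      fits[[cond]] <- scan_periods(series_by_cond[[cond]]$y, cq$time_h,
                                   period_range_h, step_h)
    }
    shift <- NA_real_
    if (length(fits) == 2L) {
      T_ref <- fits[[1L]]$period_h
      fb <- fit_harmonic(series_by_cond[[2L]]$y, series_by_cond[[2L]]$t,
                         T_ref)
      shift <- tryCatch(acrophase_shift(fits[[1L]], fb),
                        error = function(e) NA_real_)
    }
    out[[gene]] <- list(
      fits = fits,
      rhythmic = vapply(fits, function(f) f$p_value < alpha, logical(1)),
      acrophase_shift_h = shift)
  }
  out
}
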