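#' Default circadian sampling grid
#'
#' Nine samples collected every 3 h from 6 h to 30 h after synchronization,
#' one array per time point — the sampling design the generator emulates.
#'
#' @return Numeric vector of hours.
#' @export
default_times_h <- function() seq(6, 30, by = 3)

#' Simulate a rhythmic expression time-course matrix with ground truth
#'
#' Oscillating genes follow
#' \eqn{m + A\cos(2\pi (t - \varphi)/T) + N(0, \sigma^2)} on the log2 scale;
#' non-oscillators are mesor plus noise. Oscillator status is assigned to the
#' first `ceiling(frac_osc * n_genes)` genes after a seeded shuffle, so the
#' count of true oscillators is deterministic. Periods, amplitudes, mesors
#' and acrophases are drawn uniformly from their ranges.
#'
#' @param n_genes number of genes.
#' @param frac_osc fraction of genes oscillating, in [0, 1].
#' @param period_range_h range of true periods, hours (default 21-27 h).
#' @param amp_range range of true amplitudes, log2 units.
#' @param noise_sd Gaussian noise SD on the log2 scale (>= 0).
#' @param times_h sampling times (default [default_times_h()]).
#' @param mesor_range range of baseline log2 expression.
#' @param acrophase_range optional range for true acrophases in hours;
#'   `NULL` (default) draws uniformly over one full period.
#' @param seed integer seed; identical seeds give identical output.
#'
#' @return list with `matrix` (a [timecourse_matrix()]) and `truth`
#'   (data.frame: `gene_id`, `is_oscillating`, `period_h`, `amplitude`,
#'   `acrophase_h`, `mesor`; rhythm parameters are NA for non-oscillators).
#' @export
simulate_rhythmic_matrix <- function(n_genes, frac_osc = 0.3,
                                     period_range_h = c(21, 27),
                                     amp_range = c(1, 1), noise_sd = 0.5,
                                     times_h = default_times_h(),
                                     mesor_range = c(6, 12),
                                     acrophase_range = NULL, seed = 1L) {
  if (frac_osc < 0 || frac_osc > 1) stop("frac_osc must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(times_h) < 4L) stop("need at least 4 time points")
  set.seed(seed)
  ids <- sprintf("g%04d", seq_len(n_genes))
  n_osc <- ceiling(frac_osc * n_genes)
  osc <- logical(n_genes)
  osc[sample.int(n_genes)[seq_len(n_osc)]] <- TRUE

  mesor <- stats::runif(n_genes, mesor_range[1], mesor_range[2])
  period <- ifelse(osc, stats::runif(n_genes, period_range_h[1],
                                     period_range_h[2]), NA_real_)
  amp <- ifelse(osc, stats::runif(n_genes, amp_range[1], amp_range[2]),
                NA_real_)
  acro <- if (is.null(acrophase_range)) {
    ifelse(osc, stats::runif(n_genes) * period, NA_real_)
  } else {
    ifelse(osc, stats::runif(n_genes, acrophase_range[1],
                             acrophase_range[2]), NA_real_)
  }

  vals <- matrix(mesor, n_genes, length(times_h))
  for (i in which(osc))
    vals[i, ] <- vals[i, ] +
      amp[i] * cos(2 * pi * (times_h - acro[i]) / period[i])
  vals <- vals + matrix(stats::rnorm(n_genes * length(times_h),
                                     sd = noise_sd),
                        n_genes, length(times_h))
  truth <- data.frame(gene_id = ids, is_oscillating = osc,
                      period_h = period, amplitude = amp,
                      acrophase_h = acro, mesor = mesor,
                      stringsAsFactors = FALSE)
  stopifnot(all(is.na(truth$amplitude) | truth$amplitude >= 0),
            all(is.na(truth$acrophase_h) |
                  (truth$acrophase_h >= 0 &
                     truth$acrophase_h < truth$period_h)))
  list(matrix = timecourse_matrix(ids, times_h, vals), truth = truth)
}

#' Build a ground-truth PSI trajectory
#'
#' Helpers for [simulate_event_signals()]: constant, sinusoidal (cosine with
#' given mesor/amplitude/period/acrophase) or step trajectories, all clipped
#' nowhere — values outside [0, 1] raise an error.
#'
#' @param times_h sampling times.
#' @param type `"constant"`, `"sin"` or `"step"`.
#' @param level constant level (type `"constant"`) or pre-step level
#'   (`"step"`).
#' @param mesor,amplitude,period_h,acrophase_h cosine parameters
#'   (type `"sin"`).
#' @param step_time_h,step_to step change point and post-step level
#'   (type `"step"`).
#' @return Numeric PSI trajectory in [0, 1], one value per time.
#' @export
psi_trajectory <- function(times_h, type = c("constant", "sin", "step"),
                           level = 0.5, mesor = 0.5, amplitude = 0.3,
                           period_h = 24, acrophase_h = 0,
                           step_time_h = NULL, step_to = NULL) {
  type <- match.arg(type)
  psi <- switch(type,
    constant = rep(level, length(times_h)),
    sin = mesor + amplitude * cos(2 * pi * (times_h - acrophase_h) / period_h),
    step = ifelse(times_h < step_time_h, level, step_to))
  if (any(psi < 0 | psi > 1))
    stop("PSI trajectory leaves [0, 1]; adjust parameters")
  psi
}

#' Simulate probe-level signals for splicing events
#'
#' For each event the linear-scale abundance of the inclusion path is
#' `total_abundance * PSI(t)` and of the exclusion path
#' `total_abundance * (1 - PSI(t))`. Each probe multiplies its path abundance
#' by a fixed per-probe affinity (log-normal on the log2 scale with SD
#' `probe_affinity_sd`), and iid Gaussian noise with SD `noise_sd` is added
#' in the log2 domain. Probe intensities are returned on the log2 scale
#' (a path abundance of exactly zero yields `-Inf`).
#'
#' @param events either a list of numeric PSI trajectories (one per event,
#'   each of length `length(times_h)`, named by event id) or a single
#'   trajectory.
#' @param n_probes_per_path probes measuring each path (>= 1).
#' @param times_h sampling times; one sample per time.
#' @param probe_affinity_sd SD of per-probe log2 affinities (>= 0).
#' @param noise_sd measurement noise SD, log2 units (>= 0).
#' @param total_abundance linear-scale total transcript abundance.
#' @param seed integer seed.
#'
#' @return list with `quantifications` (named list of `event_quantification`
#'   objects, see [event_quantification()]) and `truth` (data.frame with
#'   `event_id` and one `psi_T<t>` column per time).
#' @export
simulate_event_signals <- function(events, n_probes_per_path = 3L,
                                   times_h = default_times_h(),
                                   probe_affinity_sd = 0.2, noise_sd = 0.1,
                                   total_abundance = 256, seed = 1L) {
  if (is.numeric(events)) events <- list(event1 = events)
  if (is.null(names(events)))
    names(events) <- sprintf("ev%04d", seq_along(events))
  if (n_probes_per_path < 1L) stop("need at least one probe per path")
  nt <- length(times_h)
  for (psi in events) {
    if (length(psi) != nt) stop("each PSI trajectory must match times_h")
    if (any(psi < 0 | psi > 1)) stop("PSI outside [0, 1] in event spec")
  }
  set.seed(seed)
  sample_ids <- sprintf("ZT%02g", times_h)
  quants <- vector("list", length(events))
  names(quants) <- names(events)
  for (e in seq_along(events)) {
    psi <- events[[e]]
    incl_ab <- total_abundance * psi          # linear scale per sample
    excl_ab <- total_abundance * (1 - psi)
    aff_i <- stats::rnorm(n_probes_per_path, 0, probe_affinity_sd)
    aff_e <- stats::rnorm(n_probes_per_path, 0, probe_affinity_sd)
    mk <- function(ab, aff) {
      m <- outer(aff, log2(ab), `+`)          # probes x samples, log2
      noise <- matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
      m + ifelse(is.finite(m), noise, 0)
    }
    quants[[e]] <- event_quantification(names(events)[e], sample_ids,
                                        times_h, mk(incl_ab, aff_i),
                                        mk(excl_ab, aff_e))
  }
  truth <- data.frame(event_id = names(events),
                      do.call(rbind, events), stringsAsFactors = FALSE)
  colnames(truth) <- c("event_id", sprintf("psi_T%g", times_h))
  list(quantifications = quants, truth = truth)
}

#' Simulate a labelled network with tunable cross-set enrichment
#'
#' Nodes are split into labelled groups. Each within-group node pair
#' receives an edge with probability `p_within`; each between-group pair
#' with probability `p_cross`, except pairs between the first two groups,
#' whose probability is `p_cross * enrichment` — the planted cross-set
#' signal. Additional groups (e.g. an unlabelled-background-sized `BG`
#' group) provide the resampling universe for [random_set_null()].
#'
#' @param n_per_label named integer vector of node counts per label, e.g.
#'   `c(SF = 251, NCRG = 130)` or `c(SF = 251, NCRG = 130, BG = 500)`.
#' @param p_within,p_cross Bernoulli edge probabilities in [0, 1].
#' @param enrichment multiplier on the probability of edges between the
#'   first two labels (`p_cross * enrichment` must be <= 1).
#' @param seed integer seed.
#' @return A [labelled_network()].
#' @export
simulate_labelled_network <- function(n_per_label = c(SF = 251, NCRG = 130),
                                      p_within = 0.01, p_cross = 0.0057,
                                      enrichment = 1, seed = 1L) {
  if (length(n_per_label) < 2L || is.null(names(n_per_label)))
    stop("n_per_label must be a named vector of at least two counts")
  if (any(c(p_within, p_cross) < 0) || any(c(p_within, p_cross) > 1))
    stop("probabilities must be in [0, 1]")
  p_x <- p_cross * enrichment
  if (p_x > 1) stop("p_cross * enrichment exceeds 1")
  set.seed(seed)
  labs <- names(n_per_label)
  ids <- lapply(seq_along(labs), function(k)
    sprintf("%s%03d", labs[k], seq_len(n_per_label[k])))
  pair_edges <- function(v1, v2, p) {
    if (p == 0) return(NULL)
    if (identical(v1, v2)) {
      idx <- utils::combn(length(v1), 2)
      keep <- stats::runif(ncol(idx)) < p
      if (!any(keep)) return(NULL)
      data.frame(from = v1[idx[1, keep]], to = v1[idx[2, keep]],
                 stringsAsFactors = FALSE)
    } else {
      g <- expand.grid(i = seq_along(v1), j = seq_along(v2))
      keep <- stats::runif(nrow(g)) < p
      if (!any(keep)) return(NULL)
      data.frame(from = v1[g$i[keep]], to = v2[g$j[keep]],
                 stringsAsFactors = FALSE)
    }
  }
  edges <- NULL
  for (k in seq_along(labs))
    edges <- rbind(edges, pair_edges(ids[[k]], ids[[k]], p_within))
  for (k in seq_along(labs)) for (l in seq_along(labs)) {
    if (l <= k) next
    p_kl <- if (k == 1L && l == 2L) p_x else p_cross
    edges <- rbind(edges, pair_edges(ids[[k]], ids[[l]], p_kl))
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character())
  labels <- stats::setNames(
    as.list(rep(labs, n_per_label)), unlist(ids))
  labelled_network(edges, labels = labels, keep_unlabelled = TRUE)
}

#' Simulate a qPCR CT time course from cosinor ground truth
#'
#' Relative expression follows `2^(mesor + A cos(2 pi (t - phi)/T))` on the
#' log2 scale; the target CT is derived from the reference-gene CT via the
#' amplification efficiency:
#' `CT_target(t) = ref_gene_ct - log(rel_expr(t)) / log(efficiency)`,
#' so with efficiency 2 a doubling of expression lowers CT by exactly one
#' cycle. Gaussian noise with SD `ct_noise_sd` is added on the cycle scale.
#'
#' @param genes data.frame with columns `gene_id`, `mesor`, `amplitude`,
#'   `period_h`, `acrophase_h` and optionally `condition`.
#' @param times_h sampling times.
#' @param reference_gene id used for the reference rows (default "GAPDH").
#' @param ref_gene_ct reference-gene CT, cycles.
#' @param efficiency amplification factor per cycle (> 1).
#' @param ct_noise_sd CT noise SD, cycles (>= 0).
#' @param n_replicates technical replicates per well.
#' @param seed integer seed.
#' @return CT table data.frame with columns `sample_id`, `time_h`,
#'   `condition`, `gene_id`, `replicate`, `ct`.
#' @export
simulate_qpcr_timecourse <- function(genes, times_h = default_times_h(),
                                     reference_gene = "GAPDH",
                                     ref_gene_ct = 15, efficiency = 2,
                                     ct_noise_sd = 0, n_replicates = 3L,
                                     seed = 1L) {
  if (efficiency <= 1) stop("efficiency must exceed 1")
  if (!all(c("gene_id", "mesor", "amplitude", "period_h", "acrophase_h")
           %in% colnames(genes)))
    stop("genes must carry gene_id, mesor, amplitude, period_h, acrophase_h")
  if (is.null(genes$condition)) genes$condition <- "control"
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    log2_expr <- g$mesor + g$amplitude *
      cos(2 * pi * (times_h - g$acrophase_h) / g$period_h)
    rel <- 2^log2_expr
    if (any(rel <= 0)) stop("non-positive expression for ", g$gene_id)
    ct <- ref_gene_ct - log(rel) / log(efficiency)
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_ZT%02g", g$condition, times_h),
        time_h = times_h, condition = g$condition, gene_id = g$gene_id,
        replicate = r,
        ct = ct + stats::rnorm(length(ct), 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  for (cond in unique(genes$condition)) {
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_ZT%02g", cond, times_h),
        time_h = times_h, condition = cond, gene_id = reference_gene,
        replicate = r,
        ct = ref_gene_ct + stats::rnorm(length(times_h), 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
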