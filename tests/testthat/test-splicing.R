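test_that("PSI is the inclusion share of linear-scale path medians", {
  expect_equal(estimate_psi(log2(c(2, 4, 8)), log2(c(2, 4, 8))), 0.5)
  expect_equal(estimate_psi(log2(3), log2(1)), 0.75)
  expect_equal(estimate_psi(log2(c(5, 5)), c(-Inf, -Inf)), 1.0)
  expect_error(estimate_psi(numeric(), 1), "at least one probe")
  expect_error(estimate_psi(-Inf, -Inf), "undefined PSI")
})

test_that("comparison planning pairs times into chronological bins", {
  plan <- plan_comparisons(seq(6, 30, 3), excluded = 18)
  expect_equal(plan$bins,
               list(c(6, 9), c(12, 15), c(21, 24), c(27, 30)))
  expect_equal(plan$comparisons, list(c(1, 2), c(2, 3), c(3, 4)))

  small <- plan_comparisons(c(0, 4, 8, 12))
  expect_length(small$bins, 2)
  expect_length(small$comparisons, 1)

  expect_error(plan_comparisons(seq(0, 18, 3)), "exclude")
})

test_that("the interaction test is exact under the null and detects switches", {
  t <- seq(6, 30, 3)
  # identical signals in both bins: delta 0, interaction SS 0, p 1
  sim0 <- simulate_event_signals(list(e = rep(0.5, 9)), 3,
                                 probe_affinity_sd = 0.3, noise_sd = 0,
                                 seed = 2)
  r0 <- test_event(sim0$quantifications$e, c(6, 9), c(12, 15))
  expect_equal(r0$delta_psi, 0)
  expect_equal(r0$p_value, 1)

  # clean 0.2 -> 0.8 switch: delta 0.6 and overwhelming significance
  psi <- c(rep(0.2, 4), rep(0.8, 5))
  sim1 <- simulate_event_signals(list(e = psi), 3, probe_affinity_sd = 0,
                                 noise_sd = 0, seed = 1)
  r1 <- test_event(sim1$quantifications$e, c(12, 15), c(21, 24))
  expect_equal(r1$delta_psi, 0.6)
  expect_lt(r1$p_value, 1e-4)

  expect_error(test_event(sim1$quantifications$e, c(6, 9), c(12, 16)),
               "missing")
})

test_that("interaction p is shift-invariant and delta-PSI scale-invariant", {
  t <- seq(6, 30, 3)
  psi <- psi_trajectory(t, "sin", mesor = 0.5, amplitude = 0.25)
  sim <- simulate_event_signals(list(e = psi), 3, probe_affinity_sd = 0.2,
                                noise_sd = 0.1, seed = 5)
  q <- sim$quantifications$e
  r <- test_event(q, c(6, 9), c(12, 15))

  # common additive shift of all log2 intensities
  q_shift <- event_quantification(q$event_id, q$sample_ids, q$times_h,
                                  q$incl_probes + 3, q$excl_probes + 3)
  r_shift <- test_event(q_shift, c(6, 9), c(12, 15))
  expect_equal(r_shift$p_value, r$p_value, tolerance = 1e-9)
  expect_equal(r_shift$delta_psi, r$delta_psi, tolerance = 1e-12)

  # per-sample scaling of both paths by a common linear factor
  fac <- log2(seq(1, 3, length.out = 9))
  q_scale <- event_quantification(q$event_id, q$sample_ids, q$times_h,
                                  sweep(q$incl_probes, 2, fac, `+`),
                                  sweep(q$excl_probes, 2, fac, `+`))
  r_scale <- test_event(q_scale, c(6, 9), c(12, 15))
  expect_equal(r_scale$delta_psi, r$delta_psi, tolerance = 1e-12)
})

test_that("null interaction p-values are approximately uniform", {
  sim <- simulate_event_signals(
    replicate(300, rep(0.5, 9), simplify = FALSE), 3,
    probe_affinity_sd = 0.2, noise_sd = 0.1, seed = 5)
  ps <- vapply(sim$quantifications, function(q)
    test_event(q, c(6, 9), c(12, 15))$p_value, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("event filtering uses strict thresholds and preserves order", {
  res <- data.frame(event_id = sprintf("e%02d", 1:10),
                    delta_psi = c(0.5, 0.1, -0.3, 0.05, 0.2,
                                  -0.15, 0.1001, 0.4, -0.05, 0.12),
                    p_value = c(0.001, 0.001, 0.5, 0.001, 0.009,
                                0.01, 0.005, 0.02, 0.002, 0.0099))
  kept <- filter_events(res, 0.01, 0.1)
  # brute-force enumeration of the rule
  expect_equal(kept$event_id,
               res$event_id[res$p_value < 0.01 & abs(res$delta_psi) > 0.1])
  # p at the limit and |dPSI| exactly 0.1 are both excluded
  expect_false("e02" %in% kept$event_id)
  expect_false("e06" %in% kept$event_id)
  expect_true("e07" %in% kept$event_id)

  # monotonicity: tightening both thresholds can only shrink the set
  loose <- filter_events(res, 0.02, 0.05)
  tight <- filter_events(res, 0.005, 0.2)
  expect_true(all(tight$event_id %in% loose$event_id))
})

test_that("recurrent intersection needs all comparisons and one large dPSI", {
  mk <- function(p, d) data.frame(event_id = sprintf("e%d", seq_along(p)),
                                  delta_psi = d, p_value = p)
  pc <- list(mk(c(0.005, 0.001, 0.5), c(0.05, 0.3, 0.3)),
             mk(c(0.002, 0.001, 0.001), c(0.12, 0.02, 0.3)),
             mk(c(0.009, 0.5, 0.001), c(0.03, 0.3, 0.3)))
  rec <- intersect_recurrent(pc, 0.01, 0.1)
  # e1: p < 0.01 everywhere, one |dPSI| >= 0.1 -> kept
  # e2: fails p in comparison 3; e3: fails p in comparison 1
  expect_equal(rec$event_id, "e1")
  expect_true(all(rec$recurrent))

  # boundary: |dPSI| exactly 0.1 counts (non-strict inside the intersection)
  pc2 <- list(mk(0.005, 0.1), mk(0.005, 0.05), mk(0.005, 0.0))
  expect_equal(nrow(intersect_recurrent(pc2, 0.01, 0.1)), 1L)
  # but nowhere >= 0.1 -> dropped
  pc3 <- list(mk(0.005, 0.05), mk(0.005, 0.05), mk(0.005, 0.099))
  expect_equal(nrow(intersect_recurrent(pc3, 0.01, 0.1)), 0L)

  pc_bad <- pc; pc_bad[[2]]$event_id <- c("x1", "x2", "x3")
  expect_error(intersect_recurrent(pc_bad), "mismatch")
})

test_that("variance ranking is deterministic and order-invariant", {
  res <- data.frame(event_id = c("b", "a", "c"),
                    dpsi_1 = c(0.3, 0.2, 0.0),
                    dpsi_2 = c(-0.3, 0.2, 0.0),
                    dpsi_3 = c(0.0, 0.2, 0.0))
  ranked <- rank_by_dpsi_variance(res)
  expect_equal(ranked$dpsi_variance[ranked$event_id == "b"], 0.09)
  expect_equal(ranked$event_id[1], "b")
  # zero-variance events rank last; ties broken lexicographically
  expect_equal(ranked$event_id[2:3], c("a", "c"))
  # permuting the input leaves the ranking unchanged
  expect_equal(rank_by_dpsi_variance(res[c(3, 1, 2), ])$event_id,
               ranked$event_id)
})

test_that("event classification follows the path-structure rules", {
  expect_equal(classify_event(cassette_annotation("+")), "cassette_exon")
  expect_equal(classify_event(cassette_annotation("-")), "cassette_exon")

  # terminal divergence with no downstream flank: alternative last exon
  alt_last <- event_annotation("e2", "g", "chr1", "+",
    path_inclusion = data.frame(start = c(100, 500), end = c(200, 700)),
    path_exclusion = data.frame(start = c(100, 900), end = c(200, 1000)),
    flank_intervals = data.frame(start = 100, end = 200))
  expect_equal(classify_event(alt_last), "alt_last_exon")
  # on the minus strand the same structure is an alternative first exon
  alt_first <- event_annotation("e3", "g", "chr1", "-",
    path_inclusion = alt_last$path_inclusion,
    path_exclusion = alt_last$path_exclusion,
    flank_intervals = alt_last$flank_intervals)
  expect_equal(classify_event(alt_first), "alt_first_exon")

  # single interval spanning the other path's two intervals plus gap
  ir <- event_annotation("e4", "g", "chr1", "+",
    path_inclusion = data.frame(start = 100, end = 600),
    path_exclusion = data.frame(start = c(100, 500), end = c(200, 600)))
  expect_equal(classify_event(ir), "intron_retention")

  # shared start, longer right end with a downstream flank: donor shift
  a5 <- event_annotation("e5", "g", "chr1", "+",
    path_inclusion = data.frame(start = c(100, 500), end = c(250, 600)),
    path_exclusion = data.frame(start = c(100, 500), end = c(200, 600)),
    flank_intervals = data.frame(start = 500, end = 600))
  expect_equal(classify_event(a5), "alt_5ss")
  a3 <- event_annotation("e6", "g", "chr1", "-",
    path_inclusion = a5$path_inclusion, path_exclusion = a5$path_exclusion,
    flank_intervals = a5$flank_intervals)
  expect_equal(classify_event(a3), "alt_3ss")

  # multi-interval divergence falls through to complex
  cx <- event_annotation("e7", "g", "chr1", "+",
    path_inclusion = data.frame(start = c(100, 300, 500, 700),
                                end = c(200, 400, 600, 800)),
    path_exclusion = data.frame(start = c(100, 350, 700),
                                end = c(200, 450, 800)))
  expect_equal(classify_event(cx), "complex")

  expect_error(event_annotation("e8", "g", "chr1", "+",
    path_inclusion = data.frame(start = 1, end = 2),
    path_exclusion = data.frame(start = 1, end = 2)), "identical")
})

test_that("annotated results join coordinates and types for BED export", {
  stats <- data.frame(event_id = "ev1", dpsi_1 = 0.4, dpsi_2 = -0.1,
                      dpsi_3 = 0.05, dpsi_variance = var(c(0.4, -0.1, 0.05)),
                      recurrent = TRUE)
  ann <- list(ev1 = cassette_annotation("+"))
  res <- splicing_event_result(stats, ann)
  expect_equal(res$gene_id, "gene1")
  expect_equal(res$start, 100)
  expect_equal(res$end, 600)
  expect_equal(res$event_type, "cassette_exon")
  p <- withr::local_tempfile(fileext = ".bed")
  write_events_bed(res, p)
  f <- strsplit(readLines(p)[2], "\t")[[1]]
  expect_equal(as.numeric(f[5]), 400)
})
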