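# Shared fixture builders; everything is generated in code.

tiny_timecourse <- function() {
  t <- seq(6, 30, by = 3)
  vals <- rbind(5 + cos(2 * pi * t / 24),
                7 + 0.5 * sin(2 * pi * t / 24),
                rep(6, length(t)))
  timecourse_matrix(c("gA", "gB", "gC"), t, vals)
}

# small deterministic labelled network: 5 nodes, 4 edges
tiny_network <- function() {
  labelled_network(
    data.frame(from = c("a", "a", "b", "d"),
               to   = c("b", "c", "c", "e")),
    labels = list(a = "SF", b = "NCRG", c = c("SF", "NCRG"),
                  d = "SF", e = "NCRG"))
}

# cassette-exon annotation: three exons, middle one skipped
cassette_annotation <- function(strand = "+") {
  event_annotation("ev1", "gene1", "chr1", strand,
    path_inclusion = data.frame(start = c(100, 300, 500),
                                end = c(200, 400, 600)),
    path_exclusion = data.frame(start = c(100, 500), end = c(200, 600)),
    flank_intervals = data.frame(start = c(100, 500), end = c(200, 600)))
}

# a deterministic block network with two planted communities
planted_block_network <- function(n = 30, p_in = 0.3, p_out = 0.01,
                                  seed = 5) {
  set.seed(seed)
  A <- sprintf("a%02d", seq_len(n)); B <- sprintf("b%02d", seq_len(n))
  edges <- NULL
  for (blk in list(A, B)) {
    idx <- utils::combn(n, 2)
    keep <- stats::runif(ncol(idx)) < p_in
    edges <- rbind(edges, data.frame(from = blk[idx[1, keep]],
                                     to = blk[idx[2, keep]]))
  }
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  keep <- stats::runif(nrow(g)) < p_out
  edges <- rbind(edges, data.frame(from = A[g$i[keep]], to = B[g$j[keep]]))
  labelled_network(edges,
                   labels = c(stats::setNames(as.list(rep("SF", n)), A),
                              stats::setNames(as.list(rep("NCRG", n)), B)))
}

rand_index <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  s <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2)); b <- sum(choose(colSums(tab), 2))
  (choose(n, 2) + 2 * s - a - b) / choose(n, 2)
}
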