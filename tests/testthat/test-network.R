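test_that("cross-interaction counting matches a brute-force edge scan", {
  net <- tiny_network()
  # hand count: a(SF)-b(NCRG), a(SF)-c(SF,NCRG), b(NCRG)-c(SF,NCRG),
  # d(SF)-e(NCRG); every edge has an SF side and an NCRG side here
  expect_equal(count_cross_interactions(net, "SF", "NCRG"), 4)
  expect_equal(count_cross_interactions(net, "NCRG", "SF"), 4)
  expect_error(count_cross_interactions(net, "SF", "ASG"), "unknown label")

  empty <- labelled_network(data.frame(from = character(),
                                       to = character()),
                            labels = list(x = "SF", y = "NCRG"))
  expect_equal(count_cross_interactions(empty, "SF", "NCRG"), 0)

  # seeded random network: count equals an exhaustive scan over edges
  set.seed(33)
  rnet <- simulate_labelled_network(c(SF = 30, NCRG = 20), 0.05, 0.05,
                                    1, seed = 33)
  brute <- sum(apply(rnet$edges, 1, function(e) {
    la <- rnet$labels[[e[["from"]]]]; lb <- rnet$labels[[e[["to"]]]]
    ("SF" %in% la && "NCRG" %in% lb) || ("NCRG" %in% la && "SF" %in% lb)
  }))
  expect_equal(count_cross_interactions(rnet, "SF", "NCRG"), brute)
})

test_that("mean cross-degrees divide the cross count by set sizes", {
  # worked example with the published set sizes and cross-edge count:
  # 251 SF nodes, 130 NCRG nodes, 186 cross edges
  sf <- sprintf("sf%03d", 1:251); nc <- sprintf("nc%03d", 1:130)
  edges <- data.frame(from = sf[((0:185) %% 251) + 1],
                      to = nc[((0:185) %% 130) + 1])
  net <- labelled_network(edges,
                          labels = c(stats::setNames(as.list(rep("SF", 251)),
                                                     sf),
                                     stats::setNames(as.list(rep("NCRG",
                                                                 130)),
                                                     nc)))
  expect_equal(count_cross_interactions(net, "SF", "NCRG"), 186)
  ds <- degree_summary(net, "SF", "NCRG")
  expect_equal(round(unname(ds), 2), c(0.74, 1.43))

  # conservation: mean degree times set size recovers the edge count
  expect_equal(unname(ds["SF"]) * 251, 186)
  expect_equal(unname(ds["NCRG"]) * 130, 186)

  # no cross edges -> (0, 0)
  iso <- labelled_network(data.frame(from = "a", to = "b"),
                          labels = list(a = "SF", b = "SF", z = "NCRG"))
  expect_equal(unname(degree_summary(iso, "SF", "NCRG")), c(0, 0))
  expect_error(degree_summary(iso, "SF", "ASG"), "unknown label")
})

test_that("the resampling null uses the add-one empirical p", {
  # fixed set isolated from everything: all null counts zero
  iso <- labelled_network(data.frame(from = c("n1", "b1"),
                                     to = c("n2", "b2")),
                          labels = list(s1 = "SF", s2 = "SF",
                                        n1 = "NCRG", n2 = "NCRG",
                                        b1 = "BG", b2 = "BG"))
  ns <- random_set_null(iso, "SF", "NCRG", n_resamples = 50, seed = 1)
  expect_equal(ns$null_mean, 0)
  expect_equal(ns$null_sd, 0)
  expect_equal(ns$empirical_p, 1)
  expect_equal(ns$observed_count, 0)

  # reproducible bit-exactly under the same seed
  net <- simulate_labelled_network(c(SF = 40, NCRG = 20, BG = 100),
                                   0.02, 0.02, 2, seed = 4)
  a <- random_set_null(net, "SF", "NCRG", n_resamples = 100, seed = 9)
  b <- random_set_null(net, "SF", "NCRG", n_resamples = 100, seed = 9)
  expect_identical(a, b)
  expect_gt(a$empirical_p, 0)
  expect_lte(a$empirical_p, 1)

  expect_error(random_set_null(net, "SF", "NCRG", resample_size = 1000),
               "exceeds")
})

test_that("planted cross-set enrichment is detected at the resampling floor", {
  net <- simulate_labelled_network(c(SF = 251, NCRG = 130, BG = 500),
                                   p_within = 0.01, p_cross = 0.0057,
                                   enrichment = 5, seed = 3)
  ns <- random_set_null(net, "SF", "NCRG", n_resamples = 100, seed = 3)
  expect_equal(ns$empirical_p, 1 / 101)
  expect_gt(ns$observed_count, ns$null_mean + 2 * ns$null_sd)
})

test_that("community detection separates planted blocks and components", {
  # two disjoint triangles form two clusters
  tri <- labelled_network(data.frame(
    from = c("a", "b", "c", "x", "y", "z"),
    to   = c("b", "c", "a", "y", "z", "x")))
  memb <- detect_communities(tri)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[c("a", "b", "c")])), 1L)

  # degenerate single edge: one cluster containing both nodes
  one <- labelled_network(data.frame(from = "a", to = "b"))
  expect_equal(length(unique(detect_communities(one))), 1L)

  # planted two-block structure is recovered almost perfectly
  net <- planted_block_network(n = 30, p_in = 0.3, p_out = 0.01, seed = 5)
  memb <- detect_communities(net, seed = 5)
  truth <- ifelse(grepl("^a", names(memb)), 1L, 2L)
  expect_gte(rand_index(memb, truth), 0.95)
})

test_that("over-representation p-values match exhaustive enumeration", {
  universe <- sprintf("u%02d", 1:20)
  gsc <- gene_set_collection(list(hit = universe[1:5],
                                  miss = universe[16:20]))
  res <- ora_test(universe[1:5], gsc, universe)
  # all 5 of 5 drawn inside a set of 5 from 20: p = 1 / C(20, 5)
  expect_equal(res$p_value[res$set_name == "hit"], 1 / choose(20, 5))
  # disjoint query: P[X >= 0] = 1
  expect_equal(res$p_value[res$set_name == "miss"], 1)
  expect_error(ora_test(c("zzz"), gsc, universe), "outside the universe")
  expect_error(ora_test("u01", gsc, character()), "empty universe")

  # property: hypergeometric tail equals direct combinatorial enumeration
  # for every configuration over small universes
  set.seed(77)
  for (i in 1:25) {
    U <- sample(5:25, 1)
    uni <- sprintf("g%02d", seq_len(U))
    s <- sample(U, 1); q <- sample(U, 1)
    set_genes <- sample(uni, s); query <- sample(uni, q)
    ov <- length(intersect(query, set_genes))
    res <- ora_test(query, gene_set_collection(list(S = set_genes)), uni)
    enum <- sum(vapply(ov:min(s, q), function(k)
      choose(s, k) * choose(U - s, q - k), numeric(1))) / choose(U, q)
    expect_equal(res$p_value, enum, tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  # independent step-up oracle: sort, p * n / rank, running minimum from
  # the largest p downwards, cap at 1
  step_up <- function(p) {
    n <- length(p); o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
    adj[order(o)]
  }
  expect_equal(step_up(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  uni <- sprintf("g%02d", 1:20)
  res <- ora_test(uni[1:6],
                  gene_set_collection(list(s1 = uni[1:5], s2 = uni[3:9],
                                           s3 = uni[15:20])), uni)
  expect_equal(res$bh_adjusted_p, step_up(res$p_value))
  expect_true(all(res$bh_adjusted_p >= res$p_value))
})
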