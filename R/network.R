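#' Count interactions between two labelled node sets
#'
#' Number of network edges with one endpoint carrying `label_a` and the
#' other carrying `label_b`. An edge whose endpoints both carry both labels
#' still counts exactly once, so the count is symmetric in its labels and
#' satisfies the degree conservation identity used by [degree_summary()].
#'
#' @param net a [labelled_network()].
#' @param label_a,label_b labels present in the network.
#' @return Integer edge count.
#' @export
count_cross_interactions <- function(net, label_a, label_b) {
  stopifnot(inherits(net, "labelled_network"))
  all_labels <- unique(unlist(net$labels))
  for (l in c(label_a, label_b))
    if (!l %in% all_labels) stop("unknown label: ", l)
  ha <- node_has_label(net, label_a)
  hb <- node_has_label(net, label_b)
  f <- net$edges$from; t <- net$edges$to
  sum((ha[f] & hb[t]) | (hb[f] & ha[t]))
}

#' Mean cross-degrees between two labelled sets
#'
#' The cross-edge count divided by the number of nodes carrying each label:
#' the average number of `label_b` partners per `label_a` node and vice
#' versa. Values are returned at full precision; round only for display.
#'
#' @inheritParams count_cross_interactions
#' @return Named numeric vector of length 2 (mean cross-degree of `label_a`
#'   nodes, then of `label_b` nodes).
#' @export
degree_summary <- function(net, label_a, label_b) {
  cross <- count_cross_interactions(net, label_a, label_b)
  na <- sum(node_has_label(net, label_a))
  nb <- sum(node_has_label(net, label_b))
  if (na == 0L || nb == 0L) stop("no nodes carry label ",
                                 if (na == 0L) label_a else label_b)
  stats::setNames(c(cross / na, cross / nb), c(label_a, label_b))
}

#' Random-set resampling null for cross-set interaction counts
#'
#' Draws `n_resamples` uniform node subsets of size `resample_size` from the
#' universe of all network nodes not carrying `fixed_label`, counts the
#' edges between each subset and the `fixed_label` set, and compares the
#' observed cross-count between `fixed_label` and `observed_label` against
#' this null. The empirical p-value uses the add-one rule
#' `(1 + #\{null >= observed\}) / (n_resamples + 1)` and is therefore never
#' zero.
#'
#' @param net a [labelled_network()].
#' @param fixed_label label of the fixed set (e.g. `"SF"`).
#' @param observed_label label of the comparison set (e.g. `"NCRG"`); the
#'   observed count is [count_cross_interactions()] of the two labels.
#' @param resample_size size of each random set; defaults to the number of
#'   nodes carrying `observed_label`.
#' @param n_resamples number of random sets (default 100).
#' @param seed integer seed.
#' @return An object of class `null_summary`: list with `n_resamples`,
#'   `observed_count`, `null_mean`, `null_sd` (n - 1 denominator),
#'   `empirical_p` and the vector `null_counts`.
#' @export
random_set_null <- function(net, fixed_label, observed_label,
                            resample_size = NULL, n_resamples = 100L,
                            seed = 1L) {
  stopifnot(inherits(net, "labelled_network"))
  observed <- count_cross_interactions(net, fixed_label, observed_label)
  fixed <- node_has_label(net, fixed_label)
  universe <- net$nodes[!fixed]
  if (is.null(resample_size))
    resample_size <- sum(node_has_label(net, observed_label) & !fixed)
  if (resample_size > length(universe))
    stop("resample_size (", resample_size, ") exceeds universe size (",
         length(universe), ")")
  # edges incident to the fixed set whose other endpoint is outside it
  f_in <- fixed[net$edges$from]; t_in <- fixed[net$edges$to]
  other <- c(net$edges$to[f_in & !t_in], net$edges$from[t_in & !f_in])
  deg <- table(other)                      # cross-degree into the fixed set
  deg_vec <- stats::setNames(rep(0, length(universe)), universe)
  deg_vec[names(deg)] <- as.numeric(deg)

  set.seed(seed)
  null_counts <- vapply(seq_len(n_resamples), function(i)
    sum(deg_vec[sample.int(length(universe), resample_size)]),
    numeric(1))
  structure(list(n_resamples = n_resamples, observed_count = observed,
                 null_mean = mean(null_counts),
                 null_sd = stats::sd(null_counts),
                 empirical_p = (1 + sum(null_counts >= observed)) /
                   (n_resamples + 1),
                 null_counts = null_counts),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "null_summary: observed %d vs %.1f +/- %.1f (n=%d), empirical p = %.4g\n",
    x$observed_count, x$null_mean, x$null_sd, x$n_resamples, x$empirical_p))
  invisible(x)
}

#' Community detection by greedy modularity maximization
#'
#' Partitions the largest connected component with multilevel greedy
#' modularity clustering (Louvain); every other connected component forms
#' one additional cluster of its own (so singleton components are singleton
#' clusters, and a single-edge network is one cluster holding both nodes).
#' The result is deterministic under `seed`.
#'
#' @param net a [labelled_network()].
#' @param seed integer seed controlling the algorithm's sweep order.
#' @return Named integer vector mapping node id to cluster index.
#' @export
detect_communities <- function(net, seed = 1L) {
  stopifnot(inherits(net, "labelled_network"))
  if (!length(net$nodes)) stop("network is empty")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  membership <- stats::setNames(integer(length(net$nodes)), net$nodes)
  sub <- igraph::induced_subgraph(g, which(comp$membership == main))
  set.seed(seed)
  cl <- igraph::cluster_louvain(sub)
  membership[igraph::V(sub)$name] <- igraph::membership(cl)
  k <- max(membership)
  for (cid in setdiff(seq_len(comp$no), main)) {
    k <- k + 1L
    membership[net$nodes[comp$membership == cid]] <- k
  }
  membership
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For each set, the one-sided upper-tail hypergeometric probability of
#' observing at least the seen overlap between the query and the set, both
#' intersected with the universe first; Benjamini-Hochberg adjustment is
#' applied across all tested sets (including those with zero overlap).
#'
#' @param query character vector of gene ids (must be within `universe`).
#' @param collection a [gene_set_collection()].
#' @param universe character vector of background gene ids.
#' @return data.frame sorted by p-value with columns `set_name`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `bh_adjusted_p`.
#' @export
ora_test <- function(query, collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop("query contains genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 3), collapse = ", "))
  U <- length(universe); q <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    ov <- length(intersect(query, s))
    p <- stats::phyper(ov - 1, length(s), U - length(s), q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = ov, set_size = length(s),
               query_size = q, universe_size = U, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$bh_adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$set_name), , drop = FALSE]
}
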