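#' Construct a labelled interaction network
#'
#' An undirected network over opaque node identifiers, each node carrying a
#' (possibly empty) subset of set labels such as `SF` (splicing factor),
#' `NCRG` (network of circadian regulated genes) or `ASG` (alternatively
#' spliced gene). Self-loops are dropped and duplicate edges collapsed after
#' canonical ordering of each pair.
#'
#' @param edges two-column data.frame (or matrix) of node-id pairs.
#' @param labels named list mapping node id to a character vector of labels;
#'   nodes appearing in `edges` but not in `labels` are kept with an empty
#'   label set only when `keep_unlabelled = TRUE`, otherwise dropped (their
#'   incident edges with them) with a message.
#' @param keep_unlabelled keep nodes without any label.
#'
#' @return An object of class `labelled_network` with fields `nodes`
#'   (character vector), `labels` (named list) and `edges` (data.frame with
#'   columns `from`, `to`, canonically ordered, deduplicated).
#' @export
labelled_network <- function(edges, labels = list(), keep_unlabelled = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && ncol(edges) < 2L)
    stop("edges must have two columns")
  from <- as.character(edges[[1L]])
  to <- if (ncol(edges) >= 2L) as.character(edges[[2L]]) else character()
  loops <- from == to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]

  nodes <- sort(unique(c(a, b, names(labels))))
  labels <- lapply(labels, function(l) sort(unique(as.character(l))))
  lab <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) lab[[n]] <- character()
  known <- intersect(names(labels), nodes)
  lab[known] <- labels[known]

  if (!keep_unlabelled) {
    unlab <- nodes[vapply(lab, length, 1L) == 0L]
    if (length(unlab)) {
      message(length(unlab), " unlabelled node(s) dropped")
      nodes <- setdiff(nodes, unlab)
      lab <- lab[nodes]
      keep_e <- a %in% nodes & b %in% nodes
      a <- a[keep_e]; b <- b[keep_e]
    }
  }
  structure(list(nodes = nodes, labels = lab,
                 edges = data.frame(from = a, to = b,
                                    stringsAsFactors = FALSE)),
            class = "labelled_network")
}

#' @export
print.labelled_network <- function(x, ...) {
  tab <- table(unlist(x$labels))
  cat("labelled_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  if (length(tab))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

node_has_label <- function(net, lab) {
  vapply(net$labels, function(l) lab %in% l, logical(1))
}

#' Read an interaction network with node-set labels
#'
#' @param edges_path edge list. For `dialect = "simple_tsv"` a headerless
#'   two-column TSV of node-id pairs; for `dialect = "psimitab"` a PSI-MI TAB
#'   2.5/2.7 file whose first two columns carry interactor identifiers of the
#'   form `namespace:ID` (the namespace prefix is stripped).
#' @param labels_path optional TSV mapping node id to label, one pair per
#'   row (a node may appear on several rows); labels for nodes absent from
#'   the edge list are attached as isolated nodes with a warning.
#' @param dialect `"simple_tsv"` or `"psimitab"`.
#' @param keep_unlabelled see [labelled_network()].
#' @return A [labelled_network()].
#' @export
read_network <- function(edges_path, labels_path = NULL,
                         dialect = c("simple_tsv", "psimitab"),
                         keep_unlabelled = TRUE) {
  dialect <- match.arg(dialect)
  lines <- readLines(edges_path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "simple_tsv") {
    bad <- vapply(parts, length, 1L) < 2L
    if (any(bad)) stop("edge line(s) with fewer than 2 fields: line ",
                       which(bad)[1L])
    from <- vapply(parts, `[`, "", 1L)
    to <- vapply(parts, `[`, "", 2L)
  } else {
    bad <- vapply(parts, length, 1L) < 2L
    if (any(bad)) stop("PSI-MI TAB line(s) with fewer than 2 columns: line ",
                       which(bad)[1L])
    strip_ns <- function(x) sub("^[^:]*:", "", sub("\\|.*$", "", x))
    from <- strip_ns(vapply(parts, `[`, "", 1L))
    to <- strip_ns(vapply(parts, `[`, "", 2L))
  }
  labels <- list()
  if (!is.null(labels_path)) {
    ldf <- utils::read.delim(labels_path, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("node", "label"))
    absent <- setdiff(unique(ldf$node), unique(c(from, to)))
    if (length(absent))
      warning("label(s) for node(s) absent from the edge list ",
              "(attached as isolated nodes): ",
              paste(absent, collapse = ", "))
    labels <- split(ldf$label, ldf$node)
  }
  labelled_network(data.frame(from = from, to = to,
                              stringsAsFactors = FALSE),
                   labels = labels, keep_unlabelled = keep_unlabelled)
}

#' Write a labelled network as edge-list and label TSVs
#'
#' Inverse of [read_network()] with `dialect = "simple_tsv"`.
#'
#' @param net a [labelled_network()].
#' @param edges_path output edge-list path.
#' @param labels_path optional output path for the node-to-label table.
#' @export
write_network <- function(net, edges_path, labels_path = NULL) {
  stopifnot(inherits(net, "labelled_network"))
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(labels_path)) {
    nl <- lengths(net$labels)
    df <- data.frame(node = rep(names(net$labels), nl),
                     label = unlist(net$labels, use.names = FALSE),
                     stringsAsFactors = FALSE)
    utils::write.table(df, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(edges_path)
}
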