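#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (unique names, non-empty sets).
#' @param descriptions optional character vector parallel to `sets`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all sets must be named")
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup)) stop("duplicate set name(s): ", paste(unique(dup), collapse = ", "))
  if (any(lengths(sets) == 0L))
    stop("empty set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets,
                 descriptions = stats::setNames(descriptions, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets, median size",
      stats::median(lengths(x$sets)), "\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: each line is `name<TAB>description<TAB>member1<TAB>...`.
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1L], " has fewer than 3 fields")
  nm <- vapply(parts, `[`, "", 1L)
  desc <- vapply(parts, `[`, "", 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#'
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(n) {
    paste(c(n, gsc$descriptions[[n]], gsc$sets[[n]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
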