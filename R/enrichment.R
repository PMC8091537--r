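#' Build a gene-set collection
#'
#' Sets are restricted to the background universe, deduplicated, and empty
#' sets are dropped. The background should be the analyzed genes (e.g. the
#' retained protein-coding genes), not the whole genome: the test asks
#' whether a query drawn from the analyzed matrix concentrates in a set.
#'
#' @param sets Named list of character vectors.
#' @param background Character vector of universe gene symbols; default is
#'   the union of all set members.
#' @return Object of class `tlv_gene_sets`: list with `sets` and
#'   `background`.
#' @export
gene_set_collection <- function(sets, background = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set needs a name")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(background)) background <- sort(unique(unlist(sets)))
  background <- unique(as.character(background))
  sets <- lapply(sets, intersect, y = background)
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  if (!length(sets)) stop("no gene set overlaps the background universe")
  structure(list(sets = sets, background = background), class = "tlv_gene_sets")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Duplicate genes within a set are deduplicated.
#'
#' @param path Path to the GMT file.
#' @param background Optional universe (default: union of all set genes).
#' @return A `tlv_gene_sets` collection; set descriptions are kept in
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected name, description and >= 1 gene")
    }
    sets[[fields[1L]]] <- unique(fields[-(1:2)])
    desc[fields[1L]] <- fields[2L]
  }
  gsc <- gene_set_collection(sets, background = background)
  attr(gsc, "descriptions") <- desc[names(gsc$sets)]
  gsc
}

#' Write gene sets in GMT format
#'
#' @param gsc A `tlv_gene_sets` collection or named list of gene vectors.
#' @param path Output path.
#' @param descriptions Optional per-set descriptions (defaults to the set
#'   names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path, descriptions = NULL) {
  sets <- if (inherits(gsc, "tlv_gene_sets")) gsc$sets else gsc
  if (is.null(descriptions)) {
    descriptions <- attr(gsc, "descriptions")
    if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, unname(descriptions[nm]), sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_{j >= i} p_(j) * m / j`.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For each set, the probability of observing at least the seen overlap
#' between the query and the set when drawing `n` genes from the
#' background universe of size `N`:
#' `p = P(X >= k)`, `X ~ Hypergeometric(N, K, n)`, followed by
#' Benjamini-Hochberg adjustment across sets. This is a local stand-in for
#' web-database pathway enrichment; the identified sets are comparable,
#' the exact FDR machinery is not.
#'
#' @param query Character vector of gene symbols.
#' @param gsc A `tlv_gene_sets` collection.
#' @return Data frame sorted by FDR then p: `set`, `K` (set size in
#'   background), `n` (query size in background), `k` (overlap), `p`,
#'   `fdr`.
#' @export
ora <- function(query, gsc) {
  stopifnot(inherits(gsc, "tlv_gene_sets"))
  if (!length(query)) stop("empty query gene list")
  query <- unique(as.character(query))
  query <- intersect(query, gsc$background)
  if (!length(query)) stop("no query gene is in the background universe")
  N <- length(gsc$background)
  n <- length(query)
  K <- vapply(gsc$sets, length, integer(1))
  k <- vapply(gsc$sets, function(s) length(intersect(query, s)), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p <- pmin(pmax(p, 0), 1)
  out <- data.frame(set = names(gsc$sets), K = K, n = n, k = k,
                    p = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$fdr, out$p, out$set), , drop = FALSE]
}
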