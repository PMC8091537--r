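#' Per-gene positional ranks of samples
#'
#' For every gene the sample with the highest count receives position 1,
#' the second highest position 2, and so on. Ties are broken by
#' sample-identifier lexical order. Positional ranks are invariant under
#' MVA (a positive per-gene rescaling), so raw and scaled input give the
#' same table.
#'
#' @param m Gene x sample matrix or `tlv_mva`.
#' @return Integer matrix (genes x samples) of positions; each row is a
#'   permutation of `1..n`.
#' @export
positional_ranks <- function(m) {
  m <- as_count_matrix(m)
  if (nrow(m) == 0L) stop("empty matrix")
  samples <- colnames(m)
  n <- ncol(m)
  out <- matrix(0L, nrow(m), n, dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    ord <- order(-m[i, ], samples, method = "radix")
    out[i, ord] <- seq_len(n)
  }
  out
}

#' Collect an individual's top-positioned genes (scoring function)
#'
#' Starting at position cutoff `k = 1`, collects the genes in which the
#' sample holds position `<= k`, incrementing `k` until at least
#' `min_genes` genes are collected (or `k` reaches the number of
#' samples).
#'
#' @param prt Positional rank table from [positional_ranks()].
#' @param sample Sample identifier.
#' @param min_genes Minimum number of genes to collect (default 1000).
#' @return Object of class `tlv_individual`: list with `sample_id`,
#'   `rank_cutoff_used`, `collected_genes` (ordered by position, then gene
#'   identifier) and `shortfall` (`TRUE` when the matrix was too small to
#'   reach `min_genes`).
#' @export
collect_individual_genes <- function(prt, sample, min_genes = 1000L) {
  if (!sample %in% colnames(prt)) stop("unknown sample: ", sample)
  stopifnot(min_genes >= 1L)
  pos <- prt[, sample]
  n <- ncol(prt)
  counts <- cumsum(tabulate(pos, nbins = n))
  reached <- which(counts >= min_genes)
  k <- if (length(reached)) reached[1L] else n
  sel <- which(pos <= k)
  ord <- order(pos[sel], rownames(prt)[sel], method = "radix")
  genes <- rownames(prt)[sel][ord]
  structure(list(sample_id = sample,
                 rank_cutoff_used = as.integer(k),
                 collected_genes = genes,
                 shortfall = length(genes) < min_genes),
            class = "tlv_individual")
}

#' Filter an individual's collected genes by top-N tailedness thresholds
#'
#' For each supplied statistic, keeps the collected genes whose statistic
#' is greater than or equal to that statistic's top-N threshold (the value
#' of the N-th ranked gene) — the comparison is inclusive.
#'
#' @param igl `tlv_individual` from [collect_individual_genes()].
#' @param stats Data frame from [stats_table()].
#' @param top_lists Named list of `tlv_toplist` objects keyed by statistic
#'   name (typically `range_over_median`, `range_over_q3`,
#'   `excess_kurtosis`, `ratio_q4`).
#' @return The input object with an added `filtered_genes`: a named list
#'   of per-statistic gene vectors (subsets of `collected_genes`).
#' @export
filter_by_top_thresholds <- function(igl, stats, top_lists) {
  stopifnot(inherits(igl, "tlv_individual"))
  filtered <- list()
  for (nm in names(top_lists)) {
    tl <- top_lists[[nm]]
    stat <- tl$statistic
    if (!stat %in% colnames(stats)) stop("no such statistic column: ", stat)
    v <- stats[[stat]][match(igl$collected_genes, stats$gene_id)]
    keep <- !is.na(v) & v >= tl$threshold_value
    filtered[[nm]] <- igl$collected_genes[keep]
  }
  igl$filtered_genes <- filtered
  igl
}

#' Screen every individual for coordinated divergent gene programs
#'
#' Runs the per-individual scoring function across all samples: positional
#' ranks, collection of at least `min_genes` top-positioned genes, and
#' filtering by the top-`top_n` thresholds of the tailedness statistics.
#' When a gene-set collection is supplied, each per-statistic filtered
#' list is tested by over-representation analysis ([ora()]) and an
#' individual is flagged when any list reaches a best FDR at or below
#' `fdr_flag`.
#'
#' @param m Gene x sample matrix or `tlv_mva`.
#' @param stats Optional precomputed [stats_table()] (computed from `m`
#'   otherwise).
#' @param gene_sets Optional `tlv_gene_sets` collection (see
#'   [gene_set_collection()] / [read_gmt()]).
#' @param statistics Statistics used for filtering (default the four
#'   tailedness measures).
#' @param min_genes Scoring-function minimum (default 1000).
#' @param top_n Top-list size defining the thresholds (default 300).
#' @param fdr_flag FDR benchmark for flagging an individual (default
#'   1e-15).
#' @return Object of class `tlv_screen`: list with `individuals` (one
#'   entry per sample: the filtered `tlv_individual`, plus `enrichment`
#'   and `best_fdr` when gene sets were supplied), `flagged` (character
#'   vector of flagged samples) and `parameters`.
#' @export
screen_all_individuals <- function(m, stats = NULL, gene_sets = NULL,
                                   statistics = c("range_over_median",
                                                  "range_over_q3",
                                                  "excess_kurtosis",
                                                  "ratio_q4"),
                                   min_genes = 1000L, top_n = 300L,
                                   fdr_flag = 1e-15) {
  values <- as_count_matrix(m)
  if (is.null(stats)) stats <- stats_table(m)
  top_lists <- lapply(statistics, function(s) top_n_by_stat(stats, s, n = top_n))
  names(top_lists) <- statistics
  prt <- positional_ranks(values)
  individuals <- list()
  flagged <- character()
  for (smp in colnames(values)) {
    igl <- collect_individual_genes(prt, smp, min_genes = min_genes)
    igl <- filter_by_top_thresholds(igl, stats, top_lists)
    if (!is.null(gene_sets)) {
      enr <- lapply(igl$filtered_genes, function(genes) {
        genes <- intersect(genes, gene_sets$background)
        if (!length(genes)) return(NULL)   # no evidence, not an error
        ora(genes, gene_sets)
      })
      best <- suppressWarnings(min(vapply(enr, function(e) {
        if (is.null(e) || !nrow(e)) Inf else min(e$fdr)
      }, numeric(1))))
      igl$enrichment <- enr
      igl$best_fdr <- best
      if (is.finite(best) && best <= fdr_flag) flagged <- c(flagged, smp)
    }
    individuals[[smp]] <- igl
  }
  structure(list(individuals = individuals, flagged = flagged,
                 top_lists = top_lists,
                 parameters = list(statistics = statistics,
                                   min_genes = as.integer(min_genes),
                                   top_n = as.integer(top_n),
                                   fdr_flag = fdr_flag)),
            class = "tlv_screen")
}

#' @export
print.tlv_screen <- function(x, ...) {
  cat(sprintf("Individual screen: %d samples, %d flagged",
              length(x$individuals), length(x$flagged)))
  if (length(x$flagged)) cat(" (", paste(x$flagged, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}
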