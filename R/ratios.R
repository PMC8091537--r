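#' Stable reference-gene candidates
#'
#' Genes whose rank-ordered trendline is nearly perfectly linear
#' (`r_squared > r2_min`) at a workable expression level
#' (`raw_mean > raw_mean_min`) are internal-reference candidates. Given
#' several statistics tables (e.g. independent data sets), the
#' intersection of per-table qualifiers is returned, sorted by the
#' smallest per-table R-squared, descending.
#'
#' @param stats_tables A [stats_table()] data frame or a list of them;
#'   each must carry a `raw_mean` column (see `raw` in [stats_table()]).
#' @param r2_min R-squared cutoff, exclusive (default 0.96).
#' @param raw_mean_min Raw-mean cutoff, exclusive (default 5).
#' @return Data frame with `gene_id` and `min_r_squared`.
#' @export
stable_gene_candidates <- function(stats_tables, r2_min = 0.96, raw_mean_min = 5) {
  if (is.data.frame(stats_tables)) stats_tables <- list(stats_tables)
  qual <- lapply(stats_tables, function(st) {
    if (!"raw_mean" %in% colnames(st)) {
      stop("stats table lacks a raw_mean column; pass raw counts to stats_table()")
    }
    keep <- !is.na(st$r_squared) & st$r_squared > r2_min &
      !is.na(st$raw_mean) & st$raw_mean > raw_mean_min
    stats::setNames(st$r_squared[keep], st$gene_id[keep])
  })
  common <- Reduce(intersect, lapply(qual, names))
  if (!length(common)) {
    return(data.frame(gene_id = character(), min_r_squared = numeric(),
                      stringsAsFactors = FALSE))
  }
  per_table <- matrix(vapply(qual, function(q) q[common],
                             numeric(length(common))),
                      nrow = length(common))
  min_r2 <- apply(per_table, 1L, min)
  out <- data.frame(gene_id = common, min_r_squared = unname(min_r2),
                    stringsAsFactors = FALSE)
  out[order(-out$min_r_squared, out$gene_id), , drop = FALSE]
}

#' Per-sample expression ratio of two genes
#'
#' Expressing a gene relative to a stable reference cancels sample-level
#' scale (library size, spike-in calibration), so the spread of the
#' ratios isolates gene-specific variability. The fold range is the ratio
#' of the largest to the smallest per-sample ratio; the reported value is
#' rounded to the nearest integer when at least 10 and to one decimal
#' below that, alongside the raw value.
#'
#' @param m Gene x sample matrix or `tlv_mva`.
#' @param num Numerator gene identifier.
#' @param den Denominator (reference) gene identifier; must be strictly
#'   positive in every sample.
#' @return Object of class `tlv_ratio_profile`: list with `num`, `den`,
#'   `ratios` (named per-sample), `min_ratio`, `max_ratio`, `fold_range`
#'   (raw) and `fold_range_reported`.
#' @export
gene_ratio <- function(m, num, den) {
  m <- as_count_matrix(m)
  for (g in c(num, den)) {
    if (!g %in% rownames(m)) stop("gene not in matrix: ", g)
  }
  d <- m[den, ]
  if (any(d <= 0)) {
    stop("reference gene '", den, "' is not strictly positive in sample(s): ",
         paste(colnames(m)[d <= 0], collapse = ", "))
  }
  ratios <- m[num, ] / d
  fr <- max(ratios) / min(ratios)
  structure(list(num = num, den = den, ratios = ratios,
                 min_ratio = min(ratios), max_ratio = max(ratios),
                 fold_range = fr,
                 fold_range_reported = report_fold_range(fr)),
            class = "tlv_ratio_profile")
}

# presentation rounding: nearest integer at >= 10, one decimal below
report_fold_range <- function(fr) {
  if (fr >= 10) round(fr) else round(fr, 1)
}

#' @export
print.tlv_ratio_profile <- function(x, ...) {
  cat(sprintf("%s/%s ratios over %d samples: %.3g to %.3g (%gX range)\n",
              x$num, x$den, length(x$ratios), x$min_ratio, x$max_ratio,
              x$fold_range_reported))
  invisible(x)
}
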