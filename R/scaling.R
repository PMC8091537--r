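#' Median-of-ratios size factors
#'
#' Classical size-factor estimation for sequencing depth: the reference for
#' each all-positive gene is its geometric mean across samples, and the
#' size factor of a sample is the median over those genes of the
#' count/reference ratio.
#'
#' @param m Gene x sample matrix of non-negative counts.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(m) {
  m <- as_count_matrix(m)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("no gene has strictly positive counts in every sample; ",
         "apply filter_low_counts() or supply cleaner input first")
  }
  lm_ <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lm_)                      # log geometric mean
  apply(lm_, 2L, function(col) exp(stats::median(col - ref)))
}

#' Divide each sample's counts by its size factor
#'
#' @param m Gene x sample matrix.
#' @param size_factors Positive numeric vector, one per sample (defaults to
#'   [size_factors_median_of_ratios()] on `m`). Externally computed factors
#'   (e.g. from spike-in calibration) can be supplied here.
#' @return Adjusted matrix with attribute `size_factors`.
#' @export
apply_size_factors <- function(m, size_factors = NULL) {
  m <- as_count_matrix(m)
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(m)
  if (length(size_factors) != ncol(m) || any(size_factors <= 0)) {
    stop("size_factors must be one positive value per sample")
  }
  out <- sweep(m, 2L, size_factors, "/")
  attr(out, "size_factors") <- size_factors
  out
}

#' Minimum Value Adjustment (MVA) scaling
#'
#' Each gene's counts are divided by that gene's smallest count, so the
#' smallest value of every gene becomes 1 and all rank-ordered trendlines
#' share a common starting point. Because the transform is a positive
#' per-gene rescaling it preserves within-gene sample ordering and every
#' scale-free statistic (CV, skewness, kurtosis, R-squared, range ratios).
#'
#' Genes containing zeros (created by the low-count floor) have no positive
#' minimum to divide by; they are divided by their smallest *positive*
#' value instead (zeros stay 0) and flagged `zero_containing`, so both
#' keeping and excluding them downstream remain possible. All-zero genes
#' are an error — they should have been removed by [filter_low_counts()].
#'
#' @param m Gene x sample matrix (already floored, see
#'   [filter_low_counts()]).
#' @param size_factors Optional per-sample factors applied (division)
#'   before MVA; `NULL` skips the step.
#' @return Object of class `tlv_mva`: list with `values` (scaled matrix),
#'   `divisors` (per-gene divisor used), `flags` (logical
#'   `zero_containing` per gene), `size_factors` (or `NULL`) and `base`
#'   (the input matrix after size-factor adjustment).
#' @export
mva_scale <- function(m, size_factors = NULL) {
  m <- as_count_matrix(m)
  if (!is.null(size_factors)) m <- apply_size_factors(m, size_factors)
  zero_rows <- rowSums(m > 0) == 0L
  if (any(zero_rows)) {
    stop("gene(s) with all-zero counts cannot be MVA-scaled: ",
         paste(utils::head(rownames(m)[zero_rows], 5L), collapse = ", "))
  }
  divisors <- apply(m, 1L, function(x) min(x[x > 0]))
  flags <- apply(m, 1L, function(x) any(x == 0))
  structure(list(values = m / divisors,
                 divisors = stats::setNames(divisors, rownames(m)),
                 flags = stats::setNames(flags, rownames(m)),
                 size_factors = attr(m, "size_factors"),
                 base = m),
            class = "tlv_mva")
}

#' @export
print.tlv_mva <- function(x, ...) {
  cat(sprintf("MVA-scaled matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  zero-containing genes flagged: %d\n", sum(x$flags)))
  if (!is.null(x$size_factors)) {
    cat("  size factors:", paste(signif(x$size_factors, 4), collapse = " "), "\n")
  }
  invisible(x)
}
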