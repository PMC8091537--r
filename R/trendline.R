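#' Build a gene trendline (ascending rank-order profile)
#'
#' Sorts one gene's counts ascending and records which sample sits at each
#' rank. Ties are broken by sample-identifier lexical order so the
#' permutation is deterministic.
#'
#' @param values Numeric vector of one gene's counts.
#' @param sample_ids Sample identifiers (defaults to `names(values)`).
#' @param gene_id Optional gene identifier carried along.
#' @return Object of class `tlv_trendline`: list with `gene_id`,
#'   `sorted_values` and `source_sample_at_rank`.
#' @export
build_trendline <- function(values, sample_ids = names(values), gene_id = NA_character_) {
  if (length(values) < 2L) stop("a trendline needs at least 2 samples")
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_along(values))
  ord <- order(values, sample_ids, method = "radix")
  structure(list(gene_id = gene_id,
                 sorted_values = unname(values[ord]),
                 source_sample_at_rank = sample_ids[ord]),
            class = "tlv_trendline")
}

#' Inclusive linear-interpolation percentile
#'
#' The inclusive spreadsheet convention: plotting position
#' `h = p * (n - 1) + 1`, linear interpolation between the adjacent order
#' statistics. Identical to `quantile(type = 7)`.
#'
#' @param x Numeric vector, assumed sorted ascending (sorting it anyway is
#'   harmless; the interpolation only uses order statistics).
#' @param p Fraction in `[0, 1]`.
#' @return Interpolated percentile value.
#' @export
percentile_inclusive <- function(x, p) {
  if (any(p < 0 | p > 1)) stop("p must be inside [0, 1]")
  stats::quantile(x, probs = p, type = 7, names = FALSE)
}

# Vectorized statistics core: rows of `m` are genes, columns samples.
# Returns the full per-gene record data frame. `quartile_ends` is the
# number of ranks in each outer segment (default round(n/4)).
trendline_stats_core <- function(m, quartile_ends = NULL, raw_mean = NULL,
                                 zero_containing = NULL) {
  n <- ncol(m)
  g <- nrow(m)
  if (n < 2L) stop("at least 2 samples are required")
  s <- t(apply(m, 1L, sort))                       # sorted trendlines
  if (g == 1L) s <- matrix(s, nrow = 1L)
  mean_ <- rowMeans(s)
  dev <- s - mean_
  ss <- rowSums(dev^2)
  sd_ <- sqrt(ss / (n - 1L))
  cv <- ifelse(mean_ > 0, 100 * sd_ / mean_, ifelse(sd_ == 0, 0, Inf))
  min_ <- s[, 1L]
  max_ <- s[, n]
  range_ <- max_ - min_

  # inclusive (type 7) percentiles on the sorted rows, vectorized
  pct_row <- function(p) {
    h <- p * (n - 1) + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[, lo] + (h - lo) * (s[, hi] - s[, lo])
  }
  median_ <- pct_row(0.5)
  q1 <- pct_row(0.25)
  q3 <- pct_row(0.75)

  max_min_ratio <- ifelse(min_ > 0, max_ / min_, ifelse(max_ == 0, NA_real_, Inf))
  range_over_median <- ifelse(median_ > 0, range_ / median_,
                              ifelse(range_ == 0, 0, Inf))
  range_over_q3 <- ifelse(q3 > 0, range_ / q3, ifelse(range_ == 0, 0, Inf))

  constant <- sd_ == 0
  z <- dev / ifelse(constant, 1, sd_)
  # bias-corrected (spreadsheet) skewness and excess kurtosis
  skewness <- n / ((n - 1) * (n - 2)) * rowSums(z^3)
  if (n < 3L) skewness <- rep(NA_real_, g)
  if (n >= 4L) {
    kurt <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * rowSums(z^4) -
      3 * (n - 1)^2 / ((n - 2) * (n - 3))
  } else {
    kurt <- rep(NA_real_, g)
  }
  skewness[constant] <- NA_real_
  kurt[constant] <- NA_real_

  # least-squares fit of sorted value against rank 1..n
  seg_slope <- function(idx) {
    w <- idx - mean(idx)
    drop(s[, idx, drop = FALSE] %*% w) / sum(w^2)
  }
  ranks <- seq_len(n)
  slope <- seg_slope(ranks)
  var_rank <- sum((ranks - mean(ranks))^2)
  r2 <- ifelse(constant, 0, (slope^2 * var_rank) / ifelse(ss == 0, 1, ss))
  slope[constant] <- 0
  r2 <- pmin(pmax(r2, 0), 1)

  # quartile-segment slopes: Q1 = first `ends` ranks, Q4 = last `ends`,
  # middle = remainder; default ends = round(n/4) (9/17/9 for n = 35)
  if (is.null(quartile_ends)) quartile_ends <- round(n / 4)
  if (quartile_ends >= 2L && n - 2L * quartile_ends >= 2L) {
    i1 <- seq_len(quartile_ends)
    i23 <- seq.int(quartile_ends + 1L, n - quartile_ends)
    i4 <- seq.int(n - quartile_ends + 1L, n)
    slope_q1 <- seg_slope(i1)
    slope_q23 <- seg_slope(i23)
    slope_q4 <- seg_slope(i4)
    ratio_q1 <- ifelse(slope_q23 != 0, slope_q1 / slope_q23,
                       ifelse(slope_q1 == 0, NA_real_, Inf))
    ratio_q4 <- ifelse(slope_q23 != 0, slope_q4 / slope_q23,
                       ifelse(slope_q4 == 0, NA_real_, Inf))
  } else {
    slope_q1 <- slope_q23 <- slope_q4 <- ratio_q1 <- ratio_q4 <- rep(NA_real_, g)
  }

  flags <- character(g)
  add_flag <- function(flags, cond, label) {
    cond <- rep_len(cond, length(flags))
    cond[is.na(cond)] <- FALSE
    ifelse(cond, ifelse(nzchar(flags), paste(flags, label, sep = ";"), label), flags)
  }
  flags <- add_flag(flags, constant, "constant")
  flags <- add_flag(flags, min_ == 0, "zero_min")
  flags <- add_flag(flags, median_ == 0 & range_ > 0, "zero_median")
  flags <- add_flag(flags, n < 4L, "kurtosis_undefined")
  flags <- add_flag(flags, slope_q23 == 0 & (slope_q1 != 0 | slope_q4 != 0),
                    "flat_mid")
  if (!is.null(zero_containing)) {
    flags <- add_flag(flags, zero_containing, "zero_containing")
  }

  out <- data.frame(
    gene_id = rownames(m), n = n, mean = mean_, median = median_, sd = sd_,
    cv = cv, min = min_, max = max_, range = range_,
    max_min_ratio = max_min_ratio, q1_value = q1, q3_value = q3,
    range_over_median = range_over_median, range_over_q3 = range_over_q3,
    skewness = skewness, excess_kurtosis = kurt, slope = slope,
    r_squared = r2, slope_q1 = slope_q1, slope_q23 = slope_q23,
    slope_q4 = slope_q4, ratio_q1 = ratio_q1, ratio_q4 = ratio_q4,
    flags = flags, stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(raw_mean)) out$raw_mean <- unname(raw_mean)
  out
}

#' Full statistics record for one trendline
#'
#' Computes the complete per-gene statistics bundle: mean, median, sample
#' SD, CV (percent), min/max/range, max/min ratio, inclusive quartiles,
#' range/median, range/Q3, bias-corrected skewness and excess kurtosis,
#' least-squares slope and R-squared of value against rank `1..n`, and
#' quartile-segment slopes with their ratios.
#'
#' @param t A `tlv_trendline` (see [build_trendline()]) or a numeric
#'   vector.
#' @param quartile_ends Ranks in each outer quartile segment; default
#'   `round(n/4)`.
#' @return One-row data frame (see [stats_table()] for the columns).
#' @export
compute_trendline_record <- function(t, quartile_ends = NULL) {
  if (inherits(t, "tlv_trendline")) {
    v <- t$sorted_values
    id <- t$gene_id
  } else {
    v <- as.numeric(t)
    id <- NA_character_
  }
  m <- matrix(v, nrow = 1L, dimnames = list(id, NULL))
  trendline_stats_core(m, quartile_ends = quartile_ends)
}

#' Quartile-segment slopes and slope ratios
#'
#' Fits a least-squares slope separately on the first `quartile_ends`
#' ranks (Q1), the middle ranks (Q2+Q3) and the last `quartile_ends` ranks
#' (Q4) of the ascending trendline, and reports the tailedness ratios
#' `slope_q1 / slope_q23` and `slope_q4 / slope_q23`. A flat middle
#' segment makes the ratios infinite. Intended for `n >= 16`; every
#' segment must hold at least 2 points.
#'
#' @param t A `tlv_trendline` or numeric vector.
#' @param quartile_ends Ranks per outer segment; default `round(n/4)`.
#' @return List with `slope_q1`, `slope_q23`, `slope_q4`, `ratio_q1`,
#'   `ratio_q4`.
#' @export
quartile_segment_slopes <- function(t, quartile_ends = NULL) {
  v <- if (inherits(t, "tlv_trendline")) t$sorted_values else sort(as.numeric(t))
  n <- length(v)
  if (is.null(quartile_ends)) quartile_ends <- round(n / 4)
  if (quartile_ends < 2L || n - 2L * quartile_ends < 2L) {
    stop("every quartile segment needs at least 2 points (n = ", n,
         ", ends = ", quartile_ends, ")")
  }
  rec <- compute_trendline_record(v, quartile_ends = quartile_ends)
  as.list(rec[, c("slope_q1", "slope_q23", "slope_q4", "ratio_q1", "ratio_q4")])
}

#' Trendline statistics table for a whole matrix
#'
#' One [compute_trendline_record()] row per gene. When `m` is an
#' MVA-scaled object the scaled values are analyzed, the unscaled per-gene
#' mean is carried in `raw_mean`, and zero-containing genes keep their
#' flag. A plain matrix can supply `raw` explicitly for the `raw_mean`
#' column (used by reference-gene selection).
#'
#' @param m Gene x sample matrix or `tlv_mva` object.
#' @param raw Optional matrix of unscaled counts (same genes) for
#'   `raw_mean`.
#' @param quartile_ends Ranks per outer quartile segment; default
#'   `round(n/4)`.
#' @return Data frame with one row per gene and stable column order.
#' @export
stats_table <- function(m, raw = NULL, quartile_ends = NULL) {
  zero_containing <- NULL
  raw_mean <- NULL
  if (inherits(m, "tlv_mva")) {
    zero_containing <- m$flags
    raw_mean <- rowMeans(m$base)
    m <- m$values
  }
  m <- as_count_matrix(m)
  if (nrow(m) == 0L) stop("empty matrix")
  if (!is.null(raw)) {
    raw <- as_count_matrix(raw)
    raw_mean <- rowMeans(raw)[rownames(m)]
  }
  trendline_stats_core(m, quartile_ends = quartile_ends, raw_mean = raw_mean,
                       zero_containing = zero_containing)
}
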