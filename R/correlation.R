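#' Top-N genes by a trendline statistic
#'
#' Ranks genes by one column of the statistics table and returns the top
#' `n`. Infinite values (flagged ratios) sort above every finite value;
#' `NA` statistics (e.g. kurtosis of constant genes) are dropped. Ties at
#' the rank-`n` boundary are all included, then order is stabilized by
#' gene identifier, so the result is deterministic and permutation
#' invariant.
#'
#' @param stats Data frame from [stats_table()].
#' @param stat Column name to rank by.
#' @param n Number of genes requested (default 300).
#' @param direction `"largest"` (default) or `"smallest"`.
#' @return Object of class `tlv_toplist`: list with `statistic`,
#'   `direction`, `n_requested`, `gene_ids`, `values` and
#'   `threshold_value` (the statistic of the n-th ranked gene).
#' @export
top_n_by_stat <- function(stats, stat, n = 300L, direction = c("largest", "smallest")) {
  direction <- match.arg(direction)
  if (!stat %in% colnames(stats)) stop("no such statistic column: ", stat)
  v <- stats[[stat]]
  ok <- !is.na(v)
  v <- v[ok]
  ids <- stats$gene_id[ok]
  if (n > length(v)) {
    warning("requested ", n, " genes but only ", length(v),
            " have a defined '", stat, "'; returning all")
    n <- length(v)
  }
  key <- if (direction == "largest") -v else v
  ord <- order(key, ids, method = "radix")
  threshold <- v[ord][n]
  keep <- if (direction == "largest") v[ord] >= threshold else v[ord] <= threshold
  sel <- ord[keep]
  structure(list(statistic = stat, direction = direction,
                 n_requested = as.integer(n),
                 gene_ids = ids[sel],
                 values = stats::setNames(v[sel], ids[sel]),
                 threshold_value = threshold),
            class = "tlv_toplist")
}

#' @export
print.tlv_toplist <- function(x, ...) {
  cat(sprintf("Top %d genes by %s (%s); threshold %.6g; %d genes after ties\n",
              x$n_requested, x$statistic, x$direction, x$threshold_value,
              length(x$gene_ids)))
  invisible(x)
}

# rows standardized so that tcrossprod gives Pearson r
.standardize_rows <- function(m) {
  mu <- rowMeans(m)
  dev <- m - mu
  ss <- sqrt(rowSums(dev^2))
  list(z = dev / ifelse(ss == 0, 1, ss), constant = ss == 0)
}

#' Pairwise Pearson correlations, blockwise
#'
#' Computes Pearson r for every unordered gene pair, processing genes in
#' blocks so the full correlation matrix is never materialized; pairs with
#' `|r| < r_min` are discarded inside each block, keeping working memory
#' bounded for ~10^4 genes.
#'
#' @param m Gene x sample matrix or `tlv_mva`.
#' @param genes Optional subset of gene identifiers.
#' @param r_min Keep only pairs with `|r| >= r_min` (default 0 keeps all).
#' @param block_size Rows per block (default 512).
#' @return Data frame with columns `gene_a`, `gene_b`, `r`.
#' @export
pairwise_correlation <- function(m, genes = NULL, r_min = 0, block_size = 512L) {
  m <- as_count_matrix(m)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) stop("genes not in matrix: ", paste(missing, collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 3L) stop("at least 3 samples are required for correlation analysis")
  std <- .standardize_rows(m)
  if (any(std$constant)) {
    warning(sum(std$constant), " constant gene(s) excluded from correlation analysis")
    m <- m[!std$constant, , drop = FALSE]
    std$z <- std$z[!std$constant, , drop = FALSE]
  }
  z <- std$z
  g <- nrow(z)
  ids <- rownames(z)
  res <- vector("list", 0L)
  starts <- seq.int(1L, g, by = block_size)
  for (bi in starts) {
    ei <- min(bi + block_size - 1L, g)
    ri <- z[bi:ei, , drop = FALSE] %*% t(z[bi:g, , drop = FALSE])
    ia <- row(ri) + bi - 1L
    ib <- col(ri) + bi - 1L
    keep <- ia < ib & abs(ri) >= r_min
    if (any(keep)) {
      res[[length(res) + 1L]] <- data.frame(
        gene_a = ids[ia[keep]], gene_b = ids[ib[keep]],
        r = pmin(pmax(ri[keep], -1), 1), stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

# per-gene extreme correlations (max and min r against any partner),
# blockwise full pass
gene_extreme_correlations <- function(m, block_size = 512L) {
  m <- as_count_matrix(m)
  std <- .standardize_rows(m)
  if (any(std$constant)) {
    warning(sum(std$constant), " constant gene(s) excluded from correlation analysis")
  }
  z <- std$z[!std$constant, , drop = FALSE]
  g <- nrow(z)
  if (g < 2L) stop("need at least 2 non-constant genes")
  max_r <- numeric(g)
  min_r <- numeric(g)
  starts <- seq.int(1L, g, by = block_size)
  for (bi in starts) {
    ei <- min(bi + block_size - 1L, g)
    ri <- z[bi:ei, , drop = FALSE] %*% t(z)
    diag_idx <- cbind(seq_len(ei - bi + 1L), bi:ei)
    ri[diag_idx] <- NA_real_
    max_r[bi:ei] <- apply(ri, 1L, max, na.rm = TRUE)
    min_r[bi:ei] <- apply(ri, 1L, min, na.rm = TRUE)
  }
  data.frame(gene_id = rownames(z),
             max_r = pmin(max_r, 1), min_r = pmax(min_r, -1),
             stringsAsFactors = FALSE)
}

#' Calibrate correlation thresholds for a target subset size
#'
#' Reproduces the manual "adjust the input correlation values up or down"
#' procedure as a bisection: the positive threshold `hi` and negative
#' threshold `lo` are moved jointly along matched empirical quantiles of
#' the per-gene extreme correlations (each gene's strongest positive and
#' strongest negative partner correlation) until the selected gene set —
#' genes participating in at least one pair with `r >= hi` or `r <= lo` —
#' is the smallest achievable size at or above `target_size`.
#'
#' @param m Gene x sample matrix or `tlv_mva`.
#' @param target_size Desired number of selected genes.
#' @param tail_policy `"both"` (default; the two tails tightened by the
#'   same quantile), `"positive"` or `"negative"` (single-tail
#'   calibration).
#' @param block_size Block size for the correlation pass.
#' @param iterations Bisection iterations (default 60).
#' @return Object of class `tlv_corr_subset`: list with `hi`, `lo`,
#'   `selected_genes`, `pairs` (data frame of the pairs beyond the
#'   thresholds among selected genes), `target_size` and `trace` (the
#'   bisection trace: quantile level, hi, lo, size).
#' @export
calibrate_thresholds <- function(m, target_size,
                                 tail_policy = c("both", "positive", "negative"),
                                 block_size = 512L, iterations = 60L) {
  tail_policy <- match.arg(tail_policy)
  m <- as_count_matrix(m)
  ext <- gene_extreme_correlations(m, block_size = block_size)
  if (target_size > nrow(ext)) {
    warning("target_size exceeds the number of usable genes; selecting all")
    target_size <- nrow(ext)
  }
  thresholds_at <- function(t) {
    hi <- if (tail_policy == "negative") Inf else
      stats::quantile(ext$max_r, t, type = 7, names = FALSE)
    lo <- if (tail_policy == "positive") -Inf else
      -stats::quantile(-ext$min_r, t, type = 7, names = FALSE)
    c(hi = hi, lo = lo)
  }
  select_at <- function(th) {
    ext$gene_id[(ext$max_r >= th[["hi"]]) | (ext$min_r <= th[["lo"]])]
  }
  trace <- list()
  record <- function(t, th, size) {
    trace[[length(trace) + 1L]] <<- data.frame(t = t, hi = th[["hi"]],
                                               lo = th[["lo"]], size = size)
  }
  if (target_size == 0L) {
    hi <- max(ext$max_r) + 1e-9
    lo <- min(ext$min_r) - 1e-9
    return(structure(list(hi = hi, lo = lo, selected_genes = character(),
                          pairs = data.frame(gene_a = character(),
                                             gene_b = character(), r = numeric()),
                          target_size = 0L,
                          trace = data.frame(t = 1, hi = hi, lo = lo, size = 0L)),
                     class = "tlv_corr_subset"))
  }
  # size is non-increasing in t; find the largest t still meeting the target
  t_lo <- 0; t_hi <- 1
  th <- thresholds_at(1)
  size1 <- length(select_at(th))
  record(1, th, size1)
  if (size1 >= target_size) {
    t_best <- 1
  } else {
    for (i in seq_len(iterations)) {
      mid <- (t_lo + t_hi) / 2
      th <- thresholds_at(mid)
      size <- length(select_at(th))
      record(mid, th, size)
      if (size >= target_size) t_lo <- mid else t_hi <- mid
    }
    t_best <- t_lo
  }
  th <- thresholds_at(t_best)
  genes <- select_at(th)
  if (length(genes) < target_size) {
    warning("target size ", target_size, " unreachable; closest achievable is ",
            length(genes))
  }
  pairs <- pairwise_correlation(m, genes = genes, block_size = block_size)
  pairs <- pairs[pairs$r >= th[["hi"]] | pairs$r <= th[["lo"]], , drop = FALSE]
  tr <- do.call(rbind, trace)
  tr <- tr[order(tr$t), , drop = FALSE]
  structure(list(hi = th[["hi"]], lo = th[["lo"]], selected_genes = genes,
                 pairs = pairs, target_size = as.integer(target_size),
                 trace = tr),
            class = "tlv_corr_subset")
}

#' @export
print.tlv_corr_subset <- function(x, ...) {
  cat(sprintf("Correlation subset: %d genes (target %d), hi = %.6g, lo = %.6g, %d pairs\n",
              length(x$selected_genes), x$target_size, x$hi, x$lo, nrow(x$pairs)))
  invisible(x)
}

#' Seed-gene correlation cluster
#'
#' All genes correlated with a seed gene beyond `r_min` (positively or
#' negatively), sorted by `|r|` descending, seed first.
#'
#' @param x Either a pair table (`gene_a`, `gene_b`, `r`) from
#'   [pairwise_correlation()], or a gene x sample matrix / `tlv_mva`, in
#'   which case the seed's correlations are computed directly.
#' @param seed Seed gene identifier.
#' @param r_min Correlation magnitude threshold.
#' @param sign `"positive"`: partners with `r >= r_min`; `"negative"`:
#'   partners with `r <= -r_min`.
#' @return Character vector of gene identifiers, seed first, with the
#'   partner correlations in attribute `r`.
#' @export
extract_cluster <- function(x, seed, r_min, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (is.data.frame(x)) {
    hit <- x$gene_a == seed | x$gene_b == seed
    if (!any(hit) && !(seed %in% c(x$gene_a, x$gene_b))) {
      stop("seed gene not present in the pair table: ", seed)
    }
    partner <- ifelse(x$gene_a[hit] == seed, x$gene_b[hit], x$gene_a[hit])
    r <- x$r[hit]
  } else {
    m <- as_count_matrix(x)
    if (!seed %in% rownames(m)) stop("seed gene not in matrix: ", seed)
    if (stats::sd(m[seed, ]) == 0) stop("seed gene is constant: ", seed)
    std <- .standardize_rows(m)
    r_all <- drop(std$z %*% std$z[seed, ])
    r_all[std$constant] <- NA_real_
    partner <- setdiff(rownames(m), seed)
    r <- r_all[match(partner, rownames(m))]
    keep0 <- !is.na(r)
    partner <- partner[keep0]
    r <- pmin(pmax(r[keep0], -1), 1)
  }
  keep <- if (sign == "positive") r >= r_min else r <= -r_min
  partner <- partner[keep]
  r <- r[keep]
  ord <- order(-abs(r), partner, method = "radix")
  out <- c(seed, partner[ord])
  attr(out, "r") <- stats::setNames(c(1, r[ord]), out)
  out
}
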