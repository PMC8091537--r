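# Independent oracles, coded separately from the package internals.

# Direct-formula statistics of a sorted trendline, via lm()/quantile()/e1071.
oracle_record <- function(x, quartile_ends = round(length(x) / 4)) {
  x <- sort(x)
  n <- length(x)
  ranks <- seq_len(n)
  fit <- stats::lm(x ~ ranks)
  seg_fit <- function(idx) unname(stats::coef(stats::lm(x[idx] ~ idx))[2L])
  i1 <- seq_len(quartile_ends)
  i23 <- seq.int(quartile_ends + 1L, n - quartile_ends)
  i4 <- seq.int(n - quartile_ends + 1L, n)
  s1 <- seg_fit(i1); s23 <- seg_fit(i23); s4 <- seg_fit(i4)
  list(
    mean = mean(x),
    median = stats::median(x),
    sd = stats::sd(x),
    cv = 100 * stats::sd(x) / mean(x),
    min = min(x), max = max(x), range = max(x) - min(x),
    max_min_ratio = max(x) / min(x),
    q1_value = unname(stats::quantile(x, 0.25, type = 7)),
    q3_value = unname(stats::quantile(x, 0.75, type = 7)),
    range_over_median = (max(x) - min(x)) / stats::median(x),
    range_over_q3 = (max(x) - min(x)) / unname(stats::quantile(x, 0.75, type = 7)),
    skewness = e1071::skewness(x, type = 2),
    excess_kurtosis = e1071::kurtosis(x, type = 2),
    slope = unname(stats::coef(fit)[2L]),
    r_squared = summary(fit)$r.squared,
    slope_q1 = s1, slope_q23 = s23, slope_q4 = s4,
    ratio_q1 = s1 / s23, ratio_q4 = s4 / s23
  )
}

# Exhaustive enumeration of the hypergeometric upper tail: probability that
# a uniformly drawn size-n subset of 1..N overlaps the set 1..K in >= k
# elements.
oracle_hyper_enum <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# Toy matrix with an exact correlation structure: two perfect positive
# pairs that are mutual reflections (r = -1 across pairs), plus noise genes.
toy_correlation_matrix <- function(n_noise = 6L, n_samples = 12L, seed = 42L) {
  set.seed(seed)
  base <- seq_len(n_samples) + stats::rnorm(n_samples, 0, 0.3)
  m <- rbind(
    P1a = base,
    P1b = base,
    P2a = 2 * mean(base) - base,   # reflection: r = -1 with base
    P2b = 2 * mean(base) - base,
    matrix(stats::rnorm(n_noise * n_samples, 10, 1), nrow = n_noise,
           dimnames = list(sprintf("N%02d", seq_len(n_noise)), NULL))
  )
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  m
}

# Small deterministic count matrix for IO / filter tests.
toy_counts <- function() {
  matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"), c("s1", "s2")))
}
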