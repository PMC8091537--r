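test_that("trendlines sort ascending with lexical tie-breaks", {
  t1 <- build_trendline(c(s1 = 5, s2 = 2, s3 = 9))
  expect_equal(t1$sorted_values, c(2, 5, 9))
  expect_identical(t1$source_sample_at_rank, c("s2", "s1", "s3"))

  t2 <- build_trendline(c(a = 1, b = 2, c = 3))
  expect_identical(t2$source_sample_at_rank, c("a", "b", "c"))

  t3 <- build_trendline(c(s2 = 3, s1 = 3))
  expect_identical(t3$source_sample_at_rank, c("s1", "s2"))

  expect_error(build_trendline(5), "at least 2")
})

test_that("inclusive percentile follows the h = p(n-1)+1 convention", {
  expect_equal(percentile_inclusive(c(1, 2, 3, 4), 0.75), 3.25)
  x <- c(2, 7, 9, 13, 20)
  expect_equal(percentile_inclusive(x, 0), min(x))
  expect_equal(percentile_inclusive(x, 1), max(x))
  expect_equal(percentile_inclusive(c(1, 3), 0.5), 2)
  expect_error(percentile_inclusive(x, 1.2), "\\[0, 1\\]")
})

test_that("exactly linear trendlines give slope 1, R^2 1, zero skewness", {
  rec <- compute_trendline_record(1:10)
  expect_equal(rec$slope, 1)
  expect_equal(rec$r_squared, 1)
  expect_equal(rec$skewness, 0)
  expect_equal(rec$ratio_q1, 1)
  expect_equal(rec$ratio_q4, 1)
})

test_that("every statistic matches the direct-formula oracle", {
  skip_if_not_installed("e1071")
  set.seed(77)
  fields <- c("mean", "median", "sd", "cv", "min", "max", "range",
              "max_min_ratio", "q1_value", "q3_value", "range_over_median",
              "range_over_q3", "skewness", "excess_kurtosis", "slope",
              "r_squared", "slope_q1", "slope_q23", "slope_q4",
              "ratio_q1", "ratio_q4")
  for (n in c(8L, 16L, 35L)) {
    for (rep in 1:10) {
      x <- stats::rlnorm(n, meanlog = 2, sdlog = 0.7)
      rec <- compute_trendline_record(x)
      orc <- oracle_record(x)
      for (f in fields) {
        expect_equal(rec[[f]], orc[[f]], tolerance = 1e-12,
                     label = sprintf("%s (n=%d)", f, n))
      }
    }
  }
})

test_that("quartile segment slopes detect an elevated top tail", {
  # values = rank, except the top 5 of 20 are rank * 10
  v <- 1:20
  v[16:20] <- v[16:20] * 10
  qs <- quartile_segment_slopes(v)
  orc <- oracle_record(v, quartile_ends = 5)
  expect_equal(qs$slope_q1, orc$slope_q1, tolerance = 1e-12)
  expect_equal(qs$slope_q23, orc$slope_q23, tolerance = 1e-12)
  expect_equal(qs$slope_q4, orc$slope_q4, tolerance = 1e-12)
  expect_gt(qs$ratio_q4, 6)

  # flat middle with rising top tail: infinite ratio
  v2 <- c(1, 2, rep(5, 4), 6, 9)
  rec <- compute_trendline_record(v2, quartile_ends = 2)
  expect_identical(rec$ratio_q4, Inf)
  expect_match(rec$flags, "flat_mid")

  expect_error(quartile_segment_slopes(1:5), "at least 2 points")
})

test_that("constant genes are flagged with zeroed dispersion statistics", {
  rec <- compute_trendline_record(rep(4, 10))
  expect_equal(rec$sd, 0)
  expect_equal(rec$cv, 0)
  expect_equal(rec$slope, 0)
  expect_equal(rec$r_squared, 0)
  expect_match(rec$flags, "constant")
})

test_that("stats_table yields one record per gene with scale-free invariance", {
  set.seed(31)
  m <- matrix(stats::rlnorm(60 * 20, 2, 0.8), nrow = 60,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:20)))
  mva <- mva_scale(m)
  st_raw <- stats_table(m)
  st_mva <- stats_table(mva)
  expect_identical(nrow(st_raw), 60L)
  scale_free <- c("cv", "skewness", "excess_kurtosis", "r_squared",
                  "max_min_ratio", "range_over_median", "range_over_q3",
                  "ratio_q1", "ratio_q4")
  for (f in scale_free) {
    expect_equal(st_mva[[f]], st_raw[[f]], tolerance = 1e-12, label = f)
  }
  # scale-dependent statistics shrink by exactly the divisor
  expect_equal(st_mva$mean, st_raw$mean / unname(mva$divisors))
  expect_equal(st_mva$sd, st_raw$sd / unname(mva$divisors))
})

test_that("R^2 of any strictly monotone arithmetic progression is exactly 1", {
  for (n in c(5L, 16L, 35L)) {
    for (step in c(0.25, 3)) {
      rec <- compute_trendline_record(seq(2, by = step, length.out = n))
      expect_equal(rec$r_squared, 1)
    }
  }
})

test_that("raw_mean column is carried for reference-gene selection", {
  m <- toy_counts()
  mva <- mva_scale(m)
  st <- stats_table(mva)
  expect_equal(st$raw_mean, unname(rowMeans(m)))
  st2 <- stats_table(m, raw = m)
  expect_equal(st2$raw_mean, unname(rowMeans(m)))
})
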