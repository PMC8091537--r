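test_that("top-N selection handles ties, infinities and short tables", {
  st <- data.frame(gene_id = c("A", "B", "C"), x = c(5, 3, 9))
  tl <- top_n_by_stat(st, "x", n = 2)
  expect_identical(tl$gene_ids, c("C", "A"))
  expect_equal(tl$threshold_value, 5)

  st2 <- data.frame(gene_id = c("A", "B", "C"), x = c(5, 5, 9))
  tl2 <- top_n_by_stat(st2, "x", n = 2)
  expect_identical(tl2$gene_ids, c("C", "A", "B"))   # boundary ties included

  tl3 <- top_n_by_stat(st, "x", n = 3)
  expect_identical(sort(tl3$gene_ids), c("A", "B", "C"))

  st4 <- data.frame(gene_id = c("A", "B", "C"), x = c(5, Inf, 9))
  expect_identical(top_n_by_stat(st4, "x", n = 1)$gene_ids, "B")

  expect_warning(tl5 <- top_n_by_stat(st, "x", n = 10), "returning all")
  expect_identical(length(tl5$gene_ids), 3L)
  expect_error(top_n_by_stat(st, "nope"), "no such statistic")

  tl6 <- top_n_by_stat(st, "x", n = 2, direction = "smallest")
  expect_identical(tl6$gene_ids, c("B", "A"))
})

test_that("top-N selection is invariant to input row order", {
  set.seed(12)
  st <- data.frame(gene_id = sprintf("g%03d", 1:50),
                   x = sample(rep(1:10, 5)))
  ref <- top_n_by_stat(st, "x", n = 7)
  for (i in 1:5) {
    perm <- st[sample(nrow(st)), ]
    expect_identical(top_n_by_stat(perm, "x", n = 7)$gene_ids, ref$gene_ids)
  }
})

test_that("pairwise correlations match the direct Pearson oracle", {
  set.seed(21)
  m <- matrix(stats::rnorm(5 * 10), nrow = 5,
              dimnames = list(letters[1:5], sprintf("s%02d", 1:10)))
  pairs <- pairwise_correlation(m)
  expect_equal(nrow(pairs), choose(5, 2))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(pairs$r[i],
                 stats::cor(m[pairs$gene_a[i], ], m[pairs$gene_b[i], ]),
                 tolerance = 1e-12)
  }
  # block size smaller than the matrix must not change the result
  pairs_blocked <- pairwise_correlation(m, block_size = 2L)
  expect_equal(pairs_blocked[order(pairs_blocked$gene_a, pairs_blocked$gene_b), ],
               pairs[order(pairs$gene_a, pairs$gene_b), ],
               ignore_attr = TRUE)

  # duplicated gene -> r = 1; negation about the mean -> r = -1
  m2 <- rbind(g = m[1, ], dup = m[1, ], neg = 2 * mean(m[1, ]) - m[1, ])
  p2 <- pairwise_correlation(m2)
  expect_equal(p2$r[p2$gene_a == "g" & p2$gene_b == "dup"], 1)
  expect_equal(p2$r[p2$gene_a == "g" & p2$gene_b == "neg"], -1)

  expect_error(pairwise_correlation(m[, 1:2]), "3 samples")
  expect_warning(pairwise_correlation(rbind(m, flat = rep(1, 10))), "constant")
})

test_that("threshold calibration recovers exactly the engineered pairs", {
  m <- toy_correlation_matrix()
  cs <- calibrate_thresholds(m, target_size = 4)
  expect_setequal(cs$selected_genes, c("P1a", "P1b", "P2a", "P2b"))
  expect_lte(cs$hi, 1)
  expect_true(all(cs$pairs$r >= cs$hi | cs$pairs$r <= cs$lo))

  # vacuous target: thresholds sit at the least extreme per-gene values
  cs_all <- calibrate_thresholds(m, target_size = nrow(m))
  expect_identical(length(cs_all$selected_genes), nrow(m))

  # target zero: empty set, hi above every observed correlation
  cs0 <- calibrate_thresholds(m, target_size = 0)
  expect_identical(cs0$selected_genes, character())
  expect_gt(cs0$hi, max(cs$pairs$r))
})

test_that("selected-set size is monotone along the bisection trace", {
  set.seed(8)
  m <- matrix(stats::rnorm(40 * 15), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:15)))
  cs <- calibrate_thresholds(m, target_size = 10)
  tr <- cs$trace
  expect_true(all(diff(tr$hi) >= 0))
  expect_true(all(diff(tr$lo) <= 0))
  expect_true(all(diff(tr$size) <= 0))
  expect_gte(length(cs$selected_genes), 10L)
})

test_that("seed clusters recover an engineered module from noise", {
  set.seed(4)
  base <- stats::rnorm(20, 50, 10)
  module <- t(vapply(1:6, function(i) base + stats::rnorm(20, 0, 1.2),
                     numeric(20)))
  rownames(module) <- sprintf("M%d", 1:6)
  noise <- matrix(stats::rnorm(10 * 20, 50, 10), nrow = 10,
                  dimnames = list(sprintf("N%02d", 1:10), NULL))
  m <- rbind(module, noise)
  colnames(m) <- sprintf("s%02d", 1:20)
  cl <- extract_cluster(m, "M1", r_min = 0.9)
  expect_setequal(cl, rownames(module))
  expect_identical(cl[1], "M1")

  # unattainable threshold: the seed alone
  expect_identical(as.character(extract_cluster(m, "M1", r_min = 1.01)), "M1")

  # pair-table input with a duplicate gene
  pairs <- pairwise_correlation(rbind(m, M1dup = m["M1", ] ))
  cl2 <- extract_cluster(pairs, "M1", r_min = 0.999)
  expect_true("M1dup" %in% cl2)

  expect_error(extract_cluster(rbind(m, flat = rep(1, 20)), "flat", 0.9),
               "constant")
})
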