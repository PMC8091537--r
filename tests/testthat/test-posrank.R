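test_that("positional ranks assign 1 to the highest count, ties lexically", {
  m <- rbind(g = c(s1 = 5, s2 = 2, s3 = 9))
  prt <- positional_ranks(m)
  expect_equal(prt["g", ], c(s1 = 2L, s2 = 3L, s3 = 1L))

  tie <- rbind(g = c(s2 = 7, s1 = 7))
  expect_equal(positional_ranks(tie)["g", ], c(s2 = 2L, s1 = 1L))
})

test_that("positional ranks are identical on raw and MVA counts and reverse the trendline", {
  set.seed(14)
  m <- matrix(stats::rlnorm(30 * 9, 2, 1), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:9)))
  mva <- mva_scale(m)
  prt <- positional_ranks(m)
  expect_identical(positional_ranks(mva), prt)
  # descending positional order is the reverse of the ascending trendline
  for (i in c(1L, 17L, 30L)) {
    tl <- build_trendline(m[i, ])
    by_position <- colnames(m)[order(prt[i, ])]
    expect_identical(by_position, rev(tl$source_sample_at_rank))
  }
  # each position appears exactly |genes| times across the table
  expect_true(all(table(prt) == nrow(m)))
})

test_that("the scoring function expands its cutoff until the quota is met", {
  # 5 genes; s1 holds position 1 in three of them
  m <- rbind(g1 = c(s1 = 9, s2 = 1, s3 = 2),
             g2 = c(s1 = 8, s2 = 2, s3 = 1),
             g3 = c(s1 = 7, s2 = 3, s3 = 2),
             g4 = c(s1 = 1, s2 = 9, s3 = 2),
             g5 = c(s1 = 1, s2 = 2, s3 = 9))
  prt <- positional_ranks(m)
  igl <- collect_individual_genes(prt, "s1", min_genes = 3)
  expect_identical(igl$rank_cutoff_used, 1L)
  expect_setequal(igl$collected_genes, c("g1", "g2", "g3"))
  expect_false(igl$shortfall)

  # a sample never holding top positions grows its cutoff
  igl3 <- collect_individual_genes(prt, "s3", min_genes = 2)
  expect_identical(igl3$rank_cutoff_used, 2L)
  expect_setequal(igl3$collected_genes, c("g1", "g4", "g5"))

  # quota above the gene count: everything collected, flagged
  igl_all <- collect_individual_genes(prt, "s2", min_genes = 10)
  expect_identical(sort(igl_all$collected_genes), rownames(m))
  expect_true(igl_all$shortfall)
})

test_that("collection is monotone in min_genes", {
  set.seed(3)
  m <- matrix(stats::rlnorm(100 * 12, 2, 1), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:12)))
  prt <- positional_ranks(m)
  for (smp in c("s01", "s07")) {
    prev <- character()
    for (q in c(5L, 15L, 40L, 80L)) {
      cur <- collect_individual_genes(prt, smp, min_genes = q)$collected_genes
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("threshold filtering is inclusive at the boundary", {
  st <- data.frame(gene_id = c("a", "b", "c"), range_over_q3 = c(4, 5, 6))
  tl <- top_n_by_stat(st, "range_over_q3", n = 2)   # threshold 5
  igl <- structure(list(sample_id = "s", rank_cutoff_used = 1L,
                        collected_genes = c("a", "b", "c"), shortfall = FALSE),
                   class = "tlv_individual")
  out <- filter_by_top_thresholds(igl, st, list(range_over_q3 = tl))
  expect_setequal(out$filtered_genes$range_over_q3, c("b", "c"))

  igl$collected_genes <- character()
  out2 <- filter_by_top_thresholds(igl, st, list(range_over_q3 = tl))
  expect_identical(out2$filtered_genes$range_over_q3, character())

  expect_error(filter_by_top_thresholds(
    igl, st, list(x = structure(list(statistic = "nope", threshold_value = 1),
                  class = "tlv_toplist"))), "no such statistic")
})

test_that("the screen flags exactly the affected individuals on spiked data", {
  sim <- generate_counts(synthetic_config(n_genes = 1200, seed = 20))
  mva <- mva_scale(sim$counts)
  set.seed(20)
  gsc <- synthetic_gene_sets(sim$truth, rownames(sim$counts), n_random_sets = 10)
  scr <- screen_all_individuals(mva, gene_sets = gsc,
                                min_genes = 150, top_n = 60)
  expect_setequal(scr$flagged, sim$truth$affected_sample_ids)

  # ablation: with the module genes removed, nobody is flagged
  keep <- setdiff(rownames(sim$counts), sim$truth$tailed_gene_ids)
  gsc2 <- gene_set_collection(gsc$sets["random_set_01"], background = keep)
  scr2 <- screen_all_individuals(mva_scale(sim$counts[keep, ]),
                                 gene_sets = gsc2,
                                 min_genes = 150, top_n = 60)
  expect_identical(scr2$flagged, character())

  # no spiked individuals: none flagged
  sim0 <- generate_counts(synthetic_config(
    n_genes = 1200, seed = 21,
    tailed_module = list(n_genes = 14, affected_samples = 0)))
  set.seed(21)
  gsc0 <- synthetic_gene_sets(sim0$truth, rownames(sim0$counts), n_random_sets = 10)
  scr0 <- screen_all_individuals(mva_scale(sim0$counts), gene_sets = gsc0,
                                 min_genes = 150, top_n = 60)
  expect_identical(scr0$flagged, character())
})
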