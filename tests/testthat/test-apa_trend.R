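test_that("weighted_delta_length matches hand-computed weighted means", {
  # full switch between two isoforms
  expect_equal(weighted_delta_length(c(100, 300), c(1, 0), c(0, 1)), 200)
  # three isoforms: weighted means 190 (CT) vs 280 (IN)
  expect_equal(weighted_delta_length(c(100, 200, 400),
                                     c(0.5, 0.3, 0.2),
                                     c(0.2, 0.3, 0.5)), 90)
  # no usage change
  expect_equal(weighted_delta_length(c(100, 300), c(0.4, 0.6),
                                     c(0.4, 0.6)), 0)
  # single transcript: no alternative usage possible
  expect_equal(weighted_delta_length(500, 1, 1), 0)
})

test_that("weighted delta is invariant to shifting all lengths", {
  set.seed(1)
  for (i in 1:20) {
    g <- random_gene_usage()
    d0 <- weighted_delta_length(g$lengths, g$p_ct, g$p_in)
    d1 <- weighted_delta_length(g$lengths + 12345, g$p_ct, g$p_in)
    expect_equal(d0, d1, tolerance = 1e-9)
  }
})

test_that("cmh_trend_test reproduces the expansion oracle", {
  # full-switch table: r = 1, M^2 = (20 - 1) * 1
  res <- cmh_trend_test(c(10, 0), c(0, 10), c(100, 300))
  expect_equal(res$trend_r, 1)
  expect_equal(res$cmh_stat, 19)
  expect_equal(res$p_value, pchisq(19, 1, lower.tail = FALSE))
  # identical count rows: independence
  res0 <- cmh_trend_test(c(5, 5), c(5, 5), c(100, 300))
  expect_equal(res0$trend_r, 0)
  expect_equal(res0$cmh_stat, 0)
  expect_equal(res0$p_value, 1)
  # random tables vs literal expansion
  set.seed(99)
  for (i in 1:50) {
    tb <- random_count_table()
    got <- cmh_trend_test(tb$counts_ct, tb$counts_in, tb$lengths)
    exp <- cmh_expansion_oracle(tb$counts_ct, tb$counts_in, tb$lengths)
    if (is.na(exp$trend_r)) next  # degenerate: oracle variance collapse
    expect_equal(got$trend_r, exp$trend_r, tolerance = 1e-9)
    expect_equal(got$cmh_stat, exp$cmh_stat, tolerance = 1e-9)
    expect_equal(got$n, exp$n)
  }
})

test_that("cmh_trend_test skips degenerate tables with a reason", {
  res <- cmh_trend_test(c(0, 0), c(5, 5), c(100, 300))
  expect_true(is.na(res$trend_r))
  expect_match(res$reason, "zero marginal")
  res2 <- cmh_trend_test(c(3, 3), c(2, 2), c(200, 200))
  expect_match(res2$reason, "zero variance")
  expect_error(cmh_trend_test(c(-1, 2), c(1, 1), c(100, 300)),
               "non-negative")
})

test_that("BH adjustment matches the hand computation and is monotone", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.04), 0.04)
  set.seed(3)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # order-preserving under permutation of the input
  perm <- sample(50)
  expect_equal(fdr_adjust(p[perm]), q[perm])
})

test_that("mean_delta trims outliers beyond the kb cutoff", {
  md <- mean_delta(c(10, 20, 3000), outlier_kb = 1)
  expect_equal(md$mean_all, 1010)
  expect_equal(md$mean_trimmed, 15)
  md2 <- mean_delta(c(-5, 5, 40))
  expect_equal(md2$mean_all, md2$mean_trimmed)
  expect_equal(unlist(mean_delta(rep(0, 5))),
               c(mean_all = 0, mean_trimmed = 0))
  expect_error(mean_delta(numeric(0)), "no length differences")
})

test_that("global shift test behaves at the null and under shift", {
  # exactly symmetric values: no evidence of a shift
  x <- c(-(1:10) / 10, (1:10) / 10)
  expect_gt(global_shift_test(x)$p_value, 0.9)
  # all-positive values at n = 12: signed-rank null gives p < 0.01
  expect_lt(global_shift_test(rep(c(0.5, 1, 2), 4))$p_value, 0.01)
  # all-zero input is defined as p = 1
  expect_equal(global_shift_test(rep(0, 12))$p_value, 1)
  # clearly shifted samples reject at alpha = 0.05 in nearly all draws
  set.seed(21)
  rejected <- vapply(1:40, function(i)
    global_shift_test(rnorm(12, mean = 1, sd = 0.5))$p_value < 0.05,
    logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("apa_trend assembles per-gene results with FDR and classes", {
  toy <- worked_toy()
  tr <- apa_trend(toy$isoforms)
  expect_s3_class(tr, "trend_result")
  expect_equal(tr$gene_id, c("G1", "G2", "G3", "G4"))  # G5: 1 transcript
  expect_equal(tr$delta_len[tr$gene_id == "G1"], 60)
  expect_equal(tr$trend_class,
               c("positive", "positive", "none", "negative"))
  expect_equal(tr$q_value, fdr_adjust(tr$p_value))
  # cmh invariant holds on every row
  expect_equal(tr$cmh_stat, (vapply(seq_len(nrow(tr)), function(i) {
    g <- toy$isoforms[toy$isoforms$gene_id == tr$gene_id[i], ]
    sum(round(g$fpkm_CT)) + sum(round(g$fpkm_IN))
  }, numeric(1)) - 1) * tr$trend_r^2, tolerance = 1e-9)
})

test_that("count_scale grows the statistic but not the correlation", {
  tab <- make_usage_tab(c(100, 250, 900), fpkm_ct = c(6, 3, 1),
                        fpkm_in = c(1, 3, 6))
  t1 <- apa_trend(tab, count_scale = 1)
  t10 <- apa_trend(tab, count_scale = 10)
  expect_equal(t1$trend_r, t10$trend_r, tolerance = 1e-12)
  expect_gt(t10$cmh_stat, t1$cmh_stat)
})

test_that("compare_fractions detects agreement and disagreement", {
  toy <- worked_toy()
  tr <- apa_trend(toy$isoforms)
  same <- compare_fractions(tr, tr)
  expect_equal(same$trend_corr, 1)
  expect_equal(same$chi2_p, 1)
  flipped <- tr
  flipped$trend_r <- -tr$trend_r
  flipped$trend_class <- c(negative = "positive", positive = "negative",
                           none = "none")[tr$trend_class]
  flip <- compare_fractions(tr, flipped)
  expect_equal(flip$trend_corr, -1)
  expect_error(compare_fractions(tr, tr[0, ]), "shared genes")
})
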