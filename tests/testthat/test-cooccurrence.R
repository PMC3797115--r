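test_that("pairwise correlation filters pairwise-zero rows and matches hand values", {
  # 6 rows; rows 5-6 are pairwise-zero and must be excluded
  mat <- matrix(c(1, 0, 1, 0, 0, 0,
                  0, 1, 0, 1, 0, 0), ncol = 2,
                dimnames = list(paste0("t", 1:6), c("a", "b")))
  res <- pairwise_correlation(mat, "a", "b")
  expect_equal(res$n_rows_used, 4L)
  expect_equal(res$r, -1)
  # identical columns correlate perfectly
  mm <- cbind(a = c(1, 0, 1, 1, 0), b = c(1, 0, 1, 1, 0))
  rownames(mm) <- paste0("t", 1:5)
  expect_equal(pairwise_correlation(mm, "a", "b")$r, 1)
})

test_that("filtering is per-pair and never uses a third column", {
  mat <- cbind(a = c(1, 0, 0, 1), b = c(0, 1, 0, 1),
               c = c(0, 0, 1, 0))
  rownames(mat) <- paste0("t", 1:4)
  # row t3 is zero for (a, b) regardless of c's value there
  res <- pairwise_correlation(mat, "a", "b")
  expect_equal(res$n_rows_used, 3L)
  mat2 <- mat; mat2[, "c"] <- 0
  expect_equal(pairwise_correlation(mat2, "a", "b")$r, res$r)
})

test_that("degenerate pairs are flagged not-computable", {
  mat <- cbind(a = c(1, 1, 0), b = c(0, 0, 1))
  rownames(mat) <- paste0("t", 1:3)
  # only 3 surviving rows but column a is constant 1 there? construct:
  few <- cbind(a = c(1, 0, rep(0, 4)), b = c(0, 1, rep(0, 4)))
  rownames(few) <- paste0("t", 1:6)
  res <- pairwise_correlation(few, "a", "b")  # 2 surviving rows
  expect_false(res$computable)
  expect_true(is.na(res$r))
  const <- cbind(a = rep(1, 5), b = c(1, 0, 1, 0, 1))
  rownames(const) <- paste0("t", 1:5)
  expect_false(pairwise_correlation(const, "a", "b")$computable)
})

test_that("weighted correlation reduces to binary when all weights are 1", {
  set.seed(20)
  for (i in 1:20) {
    n <- 30
    # single-isoform genes: every usage proportion is exactly 1
    df <- data.frame(transcript_id = paste0("t", 1:n),
                     gene_id = paste0("g", 1:n),
                     utr3_length = sample(100:1000, n),
                     fpkm_CT = runif(n, 1, 10),
                     fpkm_IN = runif(n, 1, 10))
    tab <- isoform_usage_table(df)
    tg <- matrix(rbinom(n * 3, 1, 0.5), n, 3,
                 dimnames = list(df$transcript_id, c("a", "b", "c")))
    pairs <- cooccurrence_pairs(tg, tab, weight_condition = "IN")
    ok <- pairs$computable
    expect_equal(pairs$r_weighted[ok], pairs$r_binary[ok],
                 tolerance = 1e-12)
    expect_equal(pairs$p_weighted[ok], pairs$p_binary[ok],
                 tolerance = 1e-12)
  }
})

test_that("weighting by usage changes correlations when usage varies", {
  tab <- make_usage_tab(c(100, 300, 500), fpkm_ct = c(8, 1, 1),
                        fpkm_in = c(1, 1, 8))
  tg <- matrix(c(1, 1, 0,
                 0, 1, 1), ncol = 2,
               dimnames = list(paste0("t", 1:3), c("a", "b")))
  pairs <- cooccurrence_pairs(tg, tab, weight_condition = "IN")
  expect_false(isTRUE(all.equal(pairs$r_weighted, pairs$r_binary)))
})

test_that("all_pairs covers every computable pair symmetrically", {
  set.seed(22)
  n <- 40; m <- 5
  df <- data.frame(transcript_id = paste0("t", 1:n),
                   gene_id = paste0("g", 1:n),
                   fpkm_CT = runif(n, 1, 10), fpkm_IN = runif(n, 1, 10))
  tab <- isoform_usage_table(df)
  tg <- matrix(rbinom(n * m, 1, 0.5), n, m,
               dimnames = list(df$transcript_id, paste0("m", 1:m)))
  pairs <- cooccurrence_pairs(tg, tab)
  expect_equal(nrow(pairs), choose(m, 2))
  # symmetry: recomputing a swapped pair gives the same r
  bin <- align_targets(tg, tab)
  r_ab <- pairwise_correlation(bin, "m1", "m2")$r
  r_ba <- pairwise_correlation(bin, "m2", "m1")$r
  expect_equal(r_ab, r_ba)
  # a duplicated column tops the ranking with r = 1
  tg2 <- cbind(tg, dup = tg[, "m1"])
  pairs2 <- cooccurrence_pairs(tg2, tab)
  top <- pairs2[which.max(pairs2$r_binary), ]
  expect_equal(top$r_binary, 1)
  expect_true(all(c(top$mirna_a, top$mirna_b) %in% c("m1", "dup")))
})

test_that("presence filtering induces negative dependence between independent miRNAs", {
  # conditioning on "at least one present" makes truly independent
  # columns anti-correlated; interpretation must therefore compare
  # binary vs weighted values, not test against an independence null
  set.seed(23)
  n <- 300; m <- 6
  df <- data.frame(transcript_id = paste0("t", 1:n),
                   gene_id = paste0("g", 1:n),
                   fpkm_CT = runif(n, 1, 10), fpkm_IN = runif(n, 1, 10))
  tab <- isoform_usage_table(df)
  tg <- matrix(rbinom(n * m, 1, 0.5), n, m,
               dimnames = list(df$transcript_id, paste0("m", 1:m)))
  pairs <- cooccurrence_pairs(tg, tab)
  expect_lt(mean(pairs$r_binary), 0)
  # analytic value of the induced correlation at presence prob 1/2:
  # cov and variances of Bernoulli(2/3) pairs restricted to the union
  expect_equal(mean(pairs$r_binary), -0.5, tolerance = 0.15)
})
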