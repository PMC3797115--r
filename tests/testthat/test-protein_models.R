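test_that("base model recovers a noiseless linear relation exactly", {
  set.seed(2)
  x <- rnorm(30)
  fit <- suppressWarnings(fit_base(0.5 * x, x))
  expect_equal(unname(fit$coefficients["logfc_mrna"]), 0.5,
               tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # slope equals the closed-form cov/var on arbitrary data
  y <- 0.3 * x + rnorm(30, 0, 0.4)
  fit2 <- fit_base(y, x)
  expect_equal(unname(fit2$coefficients["logfc_mrna"]),
               cov(x, y) / var(x), tolerance = 1e-12)
  # residuals of an intercept model sum to zero
  expect_lt(abs(sum(fit2$residuals)), 1e-9)
  expect_error(fit_base(y, rep(1, 30)), "constant predictor")
  expect_error(fit_base(y[1:5], x[1:5]), "at least 10")
})

test_that("slope p-values are uniform when protein is independent of mRNA", {
  set.seed(4)
  p <- replicate(200, {
    x <- rnorm(25)
    fit_base(rnorm(25), x)$coef_p[["logfc_mrna"]]
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("BIC uses the Gaussian likelihood with the error variance counted", {
  set.seed(6)
  x <- rnorm(40); y <- 0.4 * x + rnorm(40, 0, 0.3)
  fit <- fit_base(y, x)
  expect_equal(fit$bic, stats::BIC(fit$fit), tolerance = 1e-9)
  sc <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("mA", "mB")))
  fit3 <- fit_with_mirnas(y, x, sc, c("mA", "mB"))
  expect_equal(fit3$bic, stats::BIC(fit3$fit), tolerance = 1e-9)
})

test_that("miRNA coefficients recover a planted repression effect", {
  set.seed(10)
  n <- 150
  x <- rnorm(n, 0, 1.5)
  sc <- matrix(runif(n * 3, -0.6, 0.6), n, 3,
               dimnames = list(NULL, c("miR-A", "miR-B", "miR-C")))
  y <- 0.2 * x - 2 * sc[, "miR-A"] + rnorm(n, 0, 0.05)
  fit <- fit_with_mirnas(y, x, sc, "miR-A")
  se <- summary(fit$fit)$coefficients["`miR-A`", "Std. Error"]
  expect_lt(abs(fit$coefficients[["miR-A"]] + 2), 3 * se)
  # nested models never lose R^2
  base <- fit_base(y, x)
  expect_gte(fit$r_squared, base$r_squared)
  fit2 <- fit_with_mirnas(y, x, sc, c("miR-A", "miR-B"))
  expect_gte(fit2$r_squared, fit$r_squared)
})

test_that("degenerate score columns are rejected by name", {
  set.seed(11)
  x <- rnorm(30); y <- rnorm(30)
  sc <- cbind(flat = rep(0, 30), ok = rnorm(30))
  expect_error(fit_with_mirnas(y, x, sc, "flat"), "constant")
  dup <- cbind(a = rnorm(30))
  dup <- cbind(dup, b = dup[, "a"])
  expect_error(fit_with_mirnas(y, x, dup, c("a", "b")),
               "collinear.*a.*b")
  expect_error(fit_with_mirnas(y, x, sc, character(0)), "between 1 and")
  expect_error(fit_with_mirnas(y, x, sc, "missing"), "not in score")
})

test_that("BIC search finds the planted miRNA among nulls", {
  set.seed(12)
  n <- 120; n_mir <- 50
  x <- rnorm(n, 0, 1.5)
  sc <- matrix(runif(n * n_mir, -0.5, 0.5), n, n_mir,
               dimnames = list(NULL, sprintf("m%02d", 1:n_mir)))
  hits <- vapply(1:10, function(i) {
    y <- 0.2 * x - 2 * sc[, "m01"] + rnorm(n, 0, 0.1)
    sr <- search_models(y, x, sc)
    identical(sr$models[[1]]$predictors, c("logfc_mrna", "m01"))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("search handles redundant columns and an empty significant set", {
  set.seed(14)
  n <- 60
  x <- rnorm(n)
  sc <- matrix(runif(n * 3, -0.5, 0.5), n, 3,
               dimnames = list(NULL, c("mA", "mB", "mC")))
  sc[, "mB"] <- sc[, "mA"]  # identical pair
  y <- 0.3 * x - 1.5 * sc[, "mA"] + rnorm(n, 0, 0.1)
  sr <- search_models(y, x, sc)
  best <- sr$models[[1]]$predictors
  expect_lte(sum(c("mA", "mB") %in% best), 1)  # only one twin enters
  # pure noise: no significant miRNAs, univariate ranking returned
  expect_warning(sr0 <- search_models(rnorm(n), x, sc),
                 "no univariate-significant")
  expect_identical(sr0$significant, character(0))
  expect_true(all(vapply(sr0$models, function(m)
    length(m$predictors) <= 2, logical(1))))
})

test_that("greedy forward search improves BIC monotonically", {
  set.seed(15)
  n <- 100
  x <- rnorm(n)
  sc <- matrix(runif(n * 20, -0.5, 0.5), n, 20,
               dimnames = list(NULL, sprintf("m%02d", 1:20)))
  y <- 0.3 * x - 2 * sc[, "m01"] + 1.2 * sc[, "m02"] + rnorm(n, 0, 0.1)
  sr <- search_models(y, x, sc, strategy = "greedy_forward")
  best <- sr$models[[1]]
  expect_true(all(c("m01", "m02") %in% best$predictors))
  expect_lt(best$bic, fit_base(y, x)$bic)
})

test_that("bootstrap win fractions separate signal from null miRNAs", {
  set.seed(16)
  n <- 100
  x <- rnorm(n, 0, 1.5)
  sc <- matrix(runif(n * 5, -0.5, 0.5), n, 5,
               dimnames = list(NULL, sprintf("m%d", 1:5)))
  y <- 0.2 * x - 3 * sc[, "m1"] + rnorm(n, 0, 0.05)
  bt <- bootstrap_mirna(y, x, sc, n_perm = 200, seed = 31)
  res <- bt$results
  expect_equal(res$win_fraction[res$mirna_id == "m1"], 1)
  expect_true(res$high_win[res$mirna_id == "m1"])
  # identical results under the same seed (permutation stream is seeded)
  bt2 <- bootstrap_mirna(y, x, sc, n_perm = 200, seed = 31)
  expect_identical(bt$results, bt2$results)
  expect_error(bootstrap_mirna(y, x, sc, n_perm = 50), "at least 100")
  # the high/low split feeds a Kruskal-Wallis comparison
  expect_true(is.finite(bt$kruskal_p) || is.na(bt$kruskal_p))
})

test_that("residual report ranks a planted outlier first", {
  set.seed(17)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40, 0, 0.05)
  y[7] <- y[7] - 3  # protein suppressed far below prediction
  names(y) <- names(x) <- paste0("gene", 1:40)
  rep <- residual_report(fit_base(y, x))
  expect_equal(rep$gene[1], "gene7")
  expect_lt(rep$residual[1], -2)
  expect_lt(abs(sum(rep$residual)), 1e-9)
  # perfect fit: all residuals zero
  rep0 <- residual_report(suppressWarnings(fit_base(0.5 * x, x)))
  expect_true(all(abs(rep0$residual) < 1e-12))
  expect_equal(nrow(residual_report(fit_base(y, x), top_k = 5)), 5L)
})
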