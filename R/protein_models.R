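#' Fit the base protein-vs-mRNA fold-change model
#'
#' Ordinary least squares of protein log fold-change on intercept plus
#' mRNA log fold-change. The slope measures range compression: with
#' translational efficiency decaying as a power of mRNA quantity
#' (absolute protein ~ c * mRNA^b), protein log fold-changes are exactly
#' b times the mRNA log fold-changes, so the fitted slope estimates b
#' and values well below 1 indicate strong compression.
#'
#' @param logfc_prot,logfc_mrna numeric vectors, one value per gene
#'   (same order); rows with `NA` in either are dropped.
#' @param min_genes minimum complete rows required (default 10).
#' @return An `"apa_model"` list: `predictors`, `coefficients`,
#'   `r_squared`, `bic`, `coef_p`, `n_genes`, `residuals` (named if the
#'   inputs were), and the underlying `lm` fit in `$fit`.
#' @export
fit_base <- function(logfc_prot, logfc_mrna, min_genes = 10L) {
  df <- data.frame(logfc_prot = logfc_prot, logfc_mrna = logfc_mrna)
  rownames(df) <- names(logfc_prot) %||% rownames(df)
  fit_model(df, predictors = "logfc_mrna", min_genes = min_genes)
}

#' Fit a miRNA-augmented protein fold-change model
#'
#' Adds the selected miRNAs' weighted-usage score columns to the base
#' model: `logfc_prot ~ logfc_mrna + score(miR_1) + ... + score(miR_m)`.
#' Each score term is the linear image of per-target-site exponential
#' mRNA decay, so its (negative) coefficient estimates the repression
#' strength of that miRNA.
#'
#' @param logfc_prot,logfc_mrna per-gene values (same gene order as the
#'   rows of `scores`).
#' @param scores gene x miRNA score matrix (see [usage_scores()]) whose
#'   rows match the genes.
#' @param mirna_subset 1 to `max_mirnas` miRNA ids (columns of
#'   `scores`).
#' @param max_mirnas upper bound on model size (default 5).
#' @param min_genes minimum complete rows (default 10).
#' @return An `"apa_model"` list; see [fit_base()].
#' @export
fit_with_mirnas <- function(logfc_prot, logfc_mrna, scores, mirna_subset,
                            max_mirnas = 5L, min_genes = 10L) {
  if (length(mirna_subset) < 1L || length(mirna_subset) > max_mirnas)
    stop("mirna_subset must contain between 1 and ", max_mirnas, " miRNAs")
  bad <- setdiff(mirna_subset, colnames(scores))
  if (length(bad) > 0L)
    stop("miRNA(s) not in score matrix: ", paste(bad, collapse = ", "))
  df <- data.frame(logfc_prot = logfc_prot, logfc_mrna = logfc_mrna,
                   check.names = FALSE)
  for (m in mirna_subset) df[[m]] <- scores[, m]
  rownames(df) <- names(logfc_prot) %||% rownames(scores)
  fit_model(df, predictors = c("logfc_mrna", mirna_subset),
            min_genes = min_genes)
}

# shared OLS core: complete-case fit, Gaussian BIC, collinearity checks
fit_model <- function(df, predictors, min_genes = 10L) {
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < min_genes)
    stop("only ", n, " complete gene rows; need at least ", min_genes)
  X <- df[, predictors, drop = FALSE]
  vars <- vapply(X, stats::var, numeric(1))
  if (any(vars == 0))
    stop("constant predictor(s): ",
         paste(predictors[vars == 0], collapse = ", "))
  if (ncol(X) > 1L) {
    cc <- stats::cor(X)
    cc[upper.tri(cc, diag = TRUE)] <- 0
    hit <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)
    if (nrow(hit) > 0L)
      stop("collinear predictors: ", colnames(cc)[hit[1, 2]], " and ",
           rownames(cc)[hit[1, 1]])
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = "logfc_prot")
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit)))
    stop("collinear predictors: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  k <- length(stats::coef(fit))
  # Gaussian log-likelihood BIC; +1 counts the error variance
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  bic <- -2 * ll + (k + 1) * log(n)
  coefs <- stats::coef(fit)
  names(coefs) <- gsub("`", "", names(coefs), fixed = TRUE)
  pvals <- sm$coefficients[, "Pr(>|t|)"]
  names(pvals) <- names(coefs)
  structure(list(predictors = predictors, coefficients = coefs,
                 r_squared = sm$r.squared, bic = bic, coef_p = pvals,
                 n_genes = n, residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit), fit = fit),
            class = "apa_model")
}

#' @export
print.apa_model <- function(x, ...) {
  cat("APA protein fold-change model (", x$n_genes, " genes)\n", sep = "")
  cat("  predictors:", paste(x$predictors, collapse = " + "), "\n")
  cat(sprintf("  R^2 = %.4f, BIC = %.2f\n", x$r_squared, x$bic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Search miRNA-augmented models and rank them by BIC
#'
#' Stage 1 fits a univariate model per miRNA (base predictors plus that
#' miRNA's score column) and flags the ones whose score coefficient is
#' significant after BH adjustment. Stage 2 explores multi-miRNA models
#' of size 2 to `max_size`: exhaustively over the significant set
#' (`"exhaustive_within_significant"`, the default — searching all
#' subsets of every miRNA is combinatorially infeasible), or greedily
#' forward by BIC over all miRNAs (`"greedy_forward"`). Exhaustive
#' subsets are scored with a fast least-squares BIC and only the 50
#' best are refitted as full models. The base model, every univariate
#' model, and the retained combination models are returned sorted by
#' ascending BIC.
#'
#' @param logfc_prot,logfc_mrna per-gene values aligned to `scores`
#'   rows.
#' @param scores gene x miRNA score matrix.
#' @param strategy search strategy (see above).
#' @param max_size largest miRNA subset fitted (default 5).
#' @param fdr BH threshold defining the significant set (default 0.05).
#' @param max_models cap on stage-2 model count for the exhaustive
#'   strategy; beyond it the search falls back to greedy with a warning.
#' @param min_genes minimum complete rows per fit (default 10).
#' @return list with `models` (list of `"apa_model"`, ascending BIC),
#'   `univariate` (data.frame: mirna_id, coefficient, p, q, bic,
#'   r_squared), and `significant` (character vector of miRNA ids).
#' @export
search_models <- function(logfc_prot, logfc_mrna, scores,
                          strategy = c("exhaustive_within_significant",
                                       "greedy_forward"),
                          max_size = 5L, fdr = 0.05, max_models = 1e5,
                          min_genes = 10L) {
  strategy <- match.arg(strategy)
  base <- fit_base(logfc_prot, logfc_mrna, min_genes = min_genes)
  # miRNAs with usable variance on the complete rows
  ok_rows <- stats::complete.cases(logfc_prot, logfc_mrna)
  usable <- colnames(scores)[apply(scores[ok_rows, , drop = FALSE], 2,
                                   stats::var) > 0]
  uni_fits <- stats::setNames(lapply(usable, function(m)
    tryCatch(fit_with_mirnas(logfc_prot, logfc_mrna, scores, m,
                             min_genes = min_genes),
             error = function(e) NULL)), usable)
  uni_fits <- uni_fits[!vapply(uni_fits, is.null, logical(1))]
  uni <- do.call(rbind, lapply(names(uni_fits), function(m) {
    fit <- uni_fits[[m]]
    data.frame(mirna_id = m, coefficient = unname(fit$coefficients[m]),
               p = unname(fit$coef_p[m]), bic = fit$bic,
               r_squared = fit$r_squared, stringsAsFactors = FALSE)
  }))
  if (is.null(uni) || nrow(uni) == 0L)
    return(list(models = list(base), univariate = NULL,
                significant = character(0)))
  uni$q <- fdr_adjust(uni$p)
  uni <- uni[order(uni$bic), ]
  rownames(uni) <- NULL
  sig <- uni$mirna_id[uni$q < fdr]

  combos <- list()
  if (strategy == "exhaustive_within_significant") {
    if (length(sig) == 0L) {
      warning("no univariate-significant miRNAs at FDR < ", fdr,
              "; returning univariate ranking only")
    } else {
      sizes <- 2:min(max_size, length(sig))
      n_mod <- if (length(sig) < 2) 0 else sum(choose(length(sig), sizes))
      if (n_mod > max_models) {
        warning("exhaustive search over ", n_mod,
                " models exceeds max_models; falling back to greedy")
        strategy <- "greedy_forward"
      } else if (n_mod > 0) {
        # score every subset with a fast least-squares BIC, then refit
        # only the leading subsets as full models
        cc <- stats::complete.cases(logfc_prot, logfc_mrna)
        yy <- logfc_prot[cc]; n <- sum(cc)
        base_X <- cbind(`(Intercept)` = 1, logfc_mrna = logfc_mrna[cc])
        sc_cc <- scores[cc, sig, drop = FALSE]
        sets <- list()
        for (s in sizes)
          sets <- c(sets, utils::combn(sig, s, simplify = FALSE))
        bics <- vapply(sets, function(set) {
          X <- cbind(base_X, sc_cc[, set, drop = FALSE])
          fit <- stats::lm.fit(X, yy)
          if (fit$rank < ncol(X)) return(Inf)  # collinear subset
          rss <- sum(fit$residuals^2)
          k <- ncol(X)
          n * (log(2 * pi) + log(rss / n) + 1) + (k + 1) * log(n)
        }, numeric(1))
        top <- utils::head(order(bics), 50L)
        combos <- lapply(sets[top][is.finite(bics[top])], function(set)
          tryCatch(fit_with_mirnas(logfc_prot, logfc_mrna, scores, set,
                                   max_mirnas = max_size,
                                   min_genes = min_genes),
                   error = function(e) NULL))
      }
    }
  }
  if (strategy == "greedy_forward") {
    current <- character(0)
    best_bic <- base$bic
    repeat {
      if (length(current) >= max_size) break
      cand <- setdiff(names(uni_fits), current)
      trials <- lapply(cand, function(m)
        tryCatch(fit_with_mirnas(logfc_prot, logfc_mrna, scores,
                                 c(current, m), max_mirnas = max_size,
                                 min_genes = min_genes),
                 error = function(e) NULL))
      bics <- vapply(trials, function(f)
        if (is.null(f)) Inf else f$bic, numeric(1))
      if (length(bics) == 0L || min(bics) >= best_bic) break
      best <- which.min(bics)
      current <- c(current, cand[best])
      best_bic <- bics[best]
      combos <- c(combos, trials[best])
    }
  }
  models <- c(list(base), unname(uni_fits),
              combos[!vapply(combos, is.null, logical(1))])
  models <- models[order(vapply(models, `[[`, numeric(1), "bic"))]
  list(models = models, univariate = uni, significant = sig)
}

#' Permutation bootstrap of explained variance per miRNA
#'
#' For each miRNA, refits its univariate model after randomly
#' reassigning the existing score values to genes, `n_perm` times, and
#' records how often the true model's R-squared beats the permuted one
#' (`win_fraction`). miRNAs whose signal is real win essentially always;
#' under the null the win fraction is uniform. miRNAs are then split at
#' `win_threshold` and the explained variances of the two groups
#' compared with a Kruskal-Wallis test.
#'
#' @param logfc_prot,logfc_mrna per-gene values aligned to `scores`
#'   rows.
#' @param scores gene x miRNA score matrix.
#' @param mirnas miRNAs to assess (default: all columns with variance).
#' @param n_perm permutations per miRNA (default 1000, minimum 100).
#' @param seed integer seed driving all permutations.
#' @param win_threshold win-fraction cutoff splitting high- from
#'   low-confidence miRNAs (default 0.95).
#' @return list with `results` (data.frame: mirna_id, true_r2,
#'   win_fraction, n_permutations, high_win), `kruskal_stat`,
#'   `kruskal_p` (`NA` when either group is empty), `seed`.
#' @export
bootstrap_mirna <- function(logfc_prot, logfc_mrna, scores, mirnas = NULL,
                            n_perm = 1000L, seed = 1L,
                            win_threshold = 0.95) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  ok <- stats::complete.cases(logfc_prot, logfc_mrna)
  y <- logfc_prot[ok]; x <- logfc_mrna[ok]
  sc <- scores[ok, , drop = FALSE]
  if (is.null(mirnas))
    mirnas <- colnames(sc)[apply(sc, 2, stats::var) > 0]
  set.seed(seed)
  n <- length(y)
  # hat-matrix-free R^2 via direct OLS on small design matrices
  tss <- sum((y - mean(y))^2)
  r2_of <- function(s) {
    res <- stats::lm.fit(cbind(1, x, s), y)$residuals
    1 - sum(res^2) / tss
  }
  rows <- lapply(mirnas, function(m) {
    s <- sc[, m]
    true_r2 <- r2_of(s)
    perm_r2 <- vapply(seq_len(n_perm),
                      function(i) r2_of(s[sample.int(n)]), numeric(1))
    data.frame(mirna_id = m, true_r2 = true_r2,
               win_fraction = mean(true_r2 > perm_r2),
               n_permutations = n_perm, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$high_win <- res$win_fraction >= win_threshold
  if (length(unique(res$high_win)) == 2L) {
    kw <- stats::kruskal.test(res$true_r2, factor(res$high_win))
    ks <- unname(kw$statistic); kp <- kw$p.value
  } else {
    ks <- NA_real_; kp <- NA_real_
  }
  list(results = res, kruskal_stat = ks, kruskal_p = kp, seed = seed,
       win_threshold = win_threshold)
}

#' Residual report for a fitted model
#'
#' The residual (observed minus predicted protein log fold-change) per
#' gene, ranked by absolute size. Large negative residuals mark genes
#' whose protein response is suppressed below what their mRNA change
#' predicts — the candidates for post-transcriptional repression; large
#' positive residuals the converse.
#'
#' @param fit an `"apa_model"`.
#' @param top_k optionally keep only the `top_k` largest absolute
#'   residuals.
#' @return data.frame: `gene`, `residual`, `fitted`, `observed`, sorted
#'   by decreasing `|residual|`.
#' @export
residual_report <- function(fit, top_k = NULL) {
  stopifnot(inherits(fit, "apa_model"))
  res <- fit$residuals
  genes <- names(res) %||% as.character(seq_along(res))
  df <- data.frame(gene = genes, residual = unname(res),
                   fitted = unname(fit$fitted),
                   observed = unname(fit$fitted + res),
                   stringsAsFactors = FALSE)
  df <- df[order(-abs(df$residual)), , drop = FALSE]
  if (!is.null(top_k)) df <- utils::head(df, top_k)
  rownames(df) <- NULL
  df
}
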