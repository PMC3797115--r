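#' Usage-weighted 3'UTR length difference for one gene
#'
#' The per-gene summary of an APA shift: each transcript's 3'UTR length
#' weighted by its change in usage proportion between conditions,
#' `sum_t len(t) * (p_IN(t) - p_CT(t))`. Because usage changes sum to
#' zero within a gene, this equals the difference of usage-weighted mean
#' 3'UTR lengths (IN minus CT) and is invariant to adding a constant to
#' all of the gene's lengths. Positive values mean longer 3'UTRs after
#' induction.
#'
#' @param lengths numeric 3'UTR lengths (bases) of the gene's transcripts.
#' @param p_ct,p_in usage proportions in the control and induced
#'   condition; each sums to 1.
#' @return Length difference in bases. Single-transcript genes return 0
#'   (no alternative usage is possible).
#' @examples
#' weighted_delta_length(c(100, 300), c(1, 0), c(0, 1))  # +200
#' @export
weighted_delta_length <- function(lengths, p_ct, p_in) {
  stopifnot(length(lengths) == length(p_ct), length(p_ct) == length(p_in))
  if (length(lengths) < 2L) return(0)
  sum(lengths * (p_in - p_ct))
}

#' Cochran-Mantel-Haenszel linear-trend test for one gene
#'
#' Treats the gene as a 2 x k contingency table: rows are conditions
#' (scored CT = 0, IN = 1), columns its transcripts (scored by 3'UTR
#' length), cells the condition-specific counts. The trend correlation
#' `r` is the count-weighted Pearson correlation between row and column
#' scores, computed in closed form from the table; the statistic is
#' `M^2 = (n - 1) r^2`, chi-square with 1 df under independence. A
#' positive `r` means longer 3'UTRs are associated with the induced
#' condition.
#'
#' @param counts_ct,counts_in non-negative counts per transcript in each
#'   condition.
#' @param lengths transcript 3'UTR lengths (the column scores).
#' @return list with `trend_r`, `cmh_stat`, `p_value`, `n` (table total)
#'   and `reason` (`NA` when computable; otherwise why the gene was
#'   skipped, with the other fields `NA`).
#' @examples
#' cmh_trend_test(c(10, 0), c(0, 10), c(100, 300))  # r = 1, M^2 = 19
#' @export
cmh_trend_test <- function(counts_ct, counts_in, lengths) {
  k <- length(lengths)
  stopifnot(length(counts_ct) == k, length(counts_in) == k, k >= 2L)
  if (any(counts_ct < 0) || any(counts_in < 0))
    stop("counts must be non-negative")
  skip <- function(reason)
    list(trend_r = NA_real_, cmh_stat = NA_real_, p_value = NA_real_,
         n = sum(counts_ct) + sum(counts_in), reason = reason)
  n <- sum(counts_ct) + sum(counts_in)
  if (n < 2) return(skip("table total < 2"))
  if (sum(counts_ct) == 0 || sum(counts_in) == 0)
    return(skip("zero marginal: one condition has no counts"))

  # closed-form count-weighted Pearson r of (row score u, column score v)
  u <- c(rep(0, k), rep(1, k))           # CT = 0, IN = 1
  v <- c(lengths, lengths)
  w <- c(counts_ct, counts_in)
  su <- sum(w * u); sv <- sum(w * v)
  suu <- sum(w * u^2) - su^2 / n
  svv <- sum(w * v^2) - sv^2 / n
  suv <- sum(w * u * v) - su * sv / n
  if (svv <= 0) return(skip("zero variance in 3'UTR lengths"))
  r <- suv / sqrt(suu * svv)
  stat <- (n - 1) * r^2
  list(trend_r = r, cmh_stat = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n = n, reason = NA_character_)
}

#' Benjamini-Hochberg q-values
#'
#' @param p numeric p-values in (0, 1].
#' @return step-up adjusted q-values, monotone in `p`.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Per-gene APA trend table
#'
#' Runs [weighted_delta_length()] and [cmh_trend_test()] for every gene
#' with at least `min_transcripts` transcripts carrying an annotated
#' 3'UTR and defined usage proportions in both conditions. Counts for
#' the contingency table are FPKM values scaled by `count_scale` and
#' rounded to the nearest integer (floored at 0); `count_scale` lets
#' users emulate deeper read depth, which grows the statistic but not
#' the trend correlation.
#'
#' @param tab an `"isoform_usage"` table with `utr3_length` filled in.
#' @param cond_ct,cond_in control and induced condition names.
#' @param count_scale multiplier applied to FPKM before rounding
#'   (default 1).
#' @param min_transcripts minimum transcripts per gene (default 2).
#' @return data.frame of class `"trend_result"`: `gene_id`,
#'   `n_transcripts`, `delta_len`, `trend_r`, `cmh_stat`, `p_value`,
#'   `q_value` (BH over testable genes), `trend_class`
#'   (positive/negative/none by the sign of `trend_r`). Genes skipped by
#'   the test keep their `delta_len` but have `NA` statistics; the skip
#'   reasons are in `attr(x, "skipped")`.
#' @export
apa_trend <- function(tab, cond_ct = "CT", cond_in = "IN",
                      count_scale = 1, min_transcripts = 2L) {
  stopifnot(inherits(tab, "isoform_usage"), count_scale > 0)
  usable <- !is.na(tab$utr3_length) &
    !is.na(tab[[paste0("p_", cond_ct)]]) &
    !is.na(tab[[paste0("p_", cond_in)]])
  tab <- tab[usable, , drop = FALSE]
  genes <- split(seq_len(nrow(tab)), tab$gene_id)
  genes <- genes[vapply(genes, length, 1L) >= min_transcripts]

  rows <- lapply(names(genes), function(g) {
    i <- genes[[g]]
    len <- tab$utr3_length[i]
    p_ct <- tab[[paste0("p_", cond_ct)]][i]
    p_in <- tab[[paste0("p_", cond_in)]][i]
    delta <- weighted_delta_length(len, p_ct, p_in)
    cct <- pmax(0, round(tab[[paste0("fpkm_", cond_ct)]][i] * count_scale))
    cin <- pmax(0, round(tab[[paste0("fpkm_", cond_in)]][i] * count_scale))
    res <- cmh_trend_test(cct, cin, len)
    data.frame(gene_id = g, n_transcripts = length(i), delta_len = delta,
               trend_r = res$trend_r, cmh_stat = res$cmh_stat,
               p_value = res$p_value, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_transcripts = integer(0),
                      delta_len = numeric(0), trend_r = numeric(0),
                      cmh_stat = numeric(0), p_value = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE)
  out$q_value <- rep(NA_real_, nrow(out))
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- fdr_adjust(out$p_value[ok])
  out$trend_class <- ifelse(is.na(out$trend_r), NA_character_,
                            ifelse(out$trend_r > 0, "positive",
                                   ifelse(out$trend_r < 0, "negative",
                                          "none")))
  skipped <- out[!ok, c("gene_id", "reason")]
  out$reason <- NULL
  rownames(out) <- NULL
  structure(out, skipped = skipped,
            class = c("trend_result", "data.frame"))
}

#' Mean 3'UTR length difference, with and without outliers
#'
#' The global summary of the APA shift: the mean of per-gene weighted
#' length differences over all genes, and again after excluding outlier
#' genes whose absolute difference exceeds `outlier_kb` kilobases
#' (default 1 kb), to avoid a handful of extreme 3'UTRs biasing the
#' mean.
#'
#' @param delta_len numeric vector of per-gene length differences
#'   (bases), or a `"trend_result"` data.frame.
#' @param outlier_kb positive cutoff in kilobases.
#' @return list with `mean_all` and `mean_trimmed` (bases).
#' @export
mean_delta <- function(delta_len, outlier_kb = 1.0) {
  if (is.data.frame(delta_len)) delta_len <- delta_len$delta_len
  stopifnot(outlier_kb > 0)
  if (length(delta_len) == 0L) stop("no length differences supplied")
  keep <- abs(delta_len) <= outlier_kb * 1000
  list(mean_all = mean(delta_len),
       mean_trimmed = if (any(keep)) mean(delta_len[keep]) else NaN)
}

#' Test for a global shift towards longer (or shorter) 3'UTRs
#'
#' One-sample Wilcoxon signed-rank test of the per-gene trend statistic
#' (or length difference) against zero. A significant positive shift
#' supports a genome-wide tendency to use longer 3'UTR isoforms after
#' induction.
#'
#' @param trend a `"trend_result"` data.frame or a numeric vector.
#' @param measure which per-gene value to test: `"trend_r"` (default) or
#'   `"delta_len"`.
#' @param alternative passed to [stats::wilcox.test()]; two-sided by
#'   default.
#' @return list with `statistic` (V), `p_value`, `n` (non-zero values
#'   used).
#' @export
global_shift_test <- function(trend, measure = c("trend_r", "delta_len"),
                              alternative = "two.sided") {
  measure <- match.arg(measure)
  x <- if (is.data.frame(trend)) trend[[measure]] else trend
  x <- x[!is.na(x)]
  if (length(x) < 10L) stop("need at least 10 genes for the global test")
  if (all(x == 0)) return(list(statistic = 0, p_value = 1, n = 0L))
  wt <- suppressWarnings(stats::wilcox.test(x, mu = 0,
                                            alternative = alternative))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = sum(x != 0))
}

#' Compare APA trends between RNA fractions
#'
#' Two complementary views of how total and polysomal fractions differ:
#' a chi-square test on the 2 x 3 table of trend-class counts (fraction
#' by negative/none/positive), and the Pearson correlation of per-gene
#' trend statistics over the shared genes.
#'
#' @param total,poly `"trend_result"` data.frames for the two fractions.
#' @return list with `chi2_stat`, `chi2_p`, `trend_corr`, `n_shared`,
#'   and `class_counts` (the 2 x 3 table).
#' @export
compare_fractions <- function(total, poly) {
  shared <- intersect(total$gene_id, poly$gene_id)
  if (length(shared) == 0L) stop("no shared genes between fractions")
  if (length(shared) < 3L) stop("need at least 3 shared genes")
  lv <- c("negative", "none", "positive")
  t1 <- total[match(shared, total$gene_id), ]
  t2 <- poly[match(shared, poly$gene_id), ]
  counts <- rbind(total = table(factor(t1$trend_class, levels = lv)),
                  polysomal = table(factor(t2$trend_class, levels = lv)))
  nz <- colSums(counts) > 0
  if (identical(t1$trend_class, t2$trend_class)) {
    chi <- list(statistic = 0, p.value = 1)
  } else {
    chi <- suppressWarnings(stats::chisq.test(counts[, nz, drop = FALSE]))
  }
  ok <- !is.na(t1$trend_r) & !is.na(t2$trend_r)
  list(chi2_stat = unname(chi$statistic), chi2_p = chi$p.value,
       trend_corr = stats::cor(t1$trend_r[ok], t2$trend_r[ok]),
       n_shared = length(shared), class_counts = counts)
}
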