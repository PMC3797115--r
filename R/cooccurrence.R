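#' Usage-weighted version of a binary target matrix
#'
#' Each transcript row of the presence/absence matrix is multiplied by
#' that transcript's usage weight: its usage proportion in the chosen
#' condition, or the usage shift `p_IN - p_CT`. A transcript used only
#' 30% of the time by its gene contributes 0.3 where the binary matrix
#' has a 1.
#'
#' @param targets binary transcript x miRNA matrix.
#' @param tab an `"isoform_usage"` table covering the transcripts.
#' @param weight_condition `"CT"`, `"IN"` (usage proportion in that
#'   condition; default `"IN"`) or `"delta"` (`p_IN - p_CT`).
#' @return Numeric matrix, same shape as `align_targets(targets, tab)`.
#' @export
weighted_target_matrix <- function(targets, tab, weight_condition = "IN") {
  stopifnot(inherits(tab, "isoform_usage"))
  tgt <- align_targets(targets, tab)
  w <- switch(weight_condition,
              CT = tab$p_CT,
              IN = tab$p_IN,
              delta = tab$p_IN - tab$p_CT,
              stop("weight_condition must be CT, IN or delta"))
  w[is.na(w)] <- 0
  tgt * w
}

#' Correlation of two miRNAs' occurrence across transcripts
#'
#' Pearson correlation of two columns of a target matrix, restricted to
#' transcripts where at least one of the pair has a binding site
#' (pairwise-zero rows, where neither miRNA is present, dominate the
#' matrix and would swamp any signal). The same presence-based filter is
#' applied whether the correlated values are the binary entries or the
#' usage-weighted ones, so weighting with all-ones weights reproduces
#' the binary result exactly.
#'
#' @param mat numeric transcript x miRNA matrix (binary or weighted).
#' @param mirna_a,mirna_b column names of the pair.
#' @param presence optional binary matrix defining the filter; defaults
#'   to `mat != 0`.
#' @param min_rows minimum surviving rows (default 3).
#' @return list: `mirna_a`, `mirna_b`, `r`, `p_value` (t-distribution,
#'   n - 2 df), `n_rows_used`, `computable` (FALSE with `r = NA` when
#'   too few rows survive or a column is constant).
#' @export
pairwise_correlation <- function(mat, mirna_a, mirna_b, presence = NULL,
                                 min_rows = 3L) {
  for (m in c(mirna_a, mirna_b))
    if (!m %in% colnames(mat)) stop("miRNA not in matrix: ", m)
  pres <- if (is.null(presence)) mat != 0 else presence != 0
  keep <- pres[, mirna_a] | pres[, mirna_b]
  x <- mat[keep, mirna_a]; y <- mat[keep, mirna_b]
  out <- list(mirna_a = mirna_a, mirna_b = mirna_b, r = NA_real_,
              p_value = NA_real_, n_rows_used = sum(keep),
              computable = FALSE)
  if (sum(keep) < min_rows) return(out)
  if (identical(as.numeric(x), as.numeric(y))) {
    # identical occurrence on every surviving row: perfect co-occurrence
    # even when the filter leaves the pair constant (all-1 rows)
    out$r <- 1; out$p_value <- 0; out$computable <- TRUE
    return(out)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) return(out)
  ct <- stats::cor.test(x, y, method = "pearson")
  out$r <- unname(ct$estimate)
  out$p_value <- ct$p.value
  out$computable <- TRUE
  out
}

#' All-pairs miRNA co-occurrence, binary and usage-weighted
#'
#' Computes [pairwise_correlation()] for every unordered miRNA pair on
#' the presence/absence matrix and on its usage-weighted counterpart,
#' using the shared presence filter, and BH-adjusts the p-values per
#' matrix type.
#'
#' @param targets binary transcript x miRNA matrix.
#' @param tab an `"isoform_usage"` table (needed for the weights).
#' @param weight_condition see [weighted_target_matrix()].
#' @param min_rows minimum surviving rows per pair (default 3).
#' @param mirnas optional subset of miRNA columns.
#' @return data.frame: `mirna_a`, `mirna_b`, `n_rows_used`, `r_binary`,
#'   `p_binary`, `q_binary`, `r_weighted`, `p_weighted`, `q_weighted`,
#'   `computable`.
#' @export
cooccurrence_pairs <- function(targets, tab, weight_condition = "IN",
                               min_rows = 3L, mirnas = NULL) {
  if (is.null(mirnas)) mirnas <- colnames(targets)
  empty <- data.frame(mirna_a = character(0), mirna_b = character(0),
                      n_rows_used = integer(0), r_binary = numeric(0),
                      p_binary = numeric(0), q_binary = numeric(0),
                      r_weighted = numeric(0), p_weighted = numeric(0),
                      q_weighted = numeric(0), computable = logical(0))
  if (length(mirnas) < 2L) return(empty)
  bin <- align_targets(targets[, mirnas, drop = FALSE], tab)
  wgt <- weighted_target_matrix(targets[, mirnas, drop = FALSE], tab,
                                weight_condition)
  pairs <- utils::combn(mirnas, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    b <- pairwise_correlation(bin, pr[1], pr[2], presence = bin,
                              min_rows = min_rows)
    w <- pairwise_correlation(wgt, pr[1], pr[2], presence = bin,
                              min_rows = min_rows)
    data.frame(mirna_a = pr[1], mirna_b = pr[2],
               n_rows_used = b$n_rows_used,
               r_binary = b$r, p_binary = b$p_value,
               r_weighted = w$r, p_weighted = w$p_value,
               computable = b$computable & w$computable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_binary <- NA_real_
  out$q_weighted <- NA_real_
  ok <- !is.na(out$p_binary)
  out$q_binary[ok] <- fdr_adjust(out$p_binary[ok])
  ok <- !is.na(out$p_weighted)
  out$q_weighted[ok] <- fdr_adjust(out$p_weighted[ok])
  out[, c("mirna_a", "mirna_b", "n_rows_used", "r_binary", "p_binary",
          "q_binary", "r_weighted", "p_weighted", "q_weighted",
          "computable")]
}
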