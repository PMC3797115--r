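#' Gene x miRNA weighted-usage score matrix
#'
#' For each gene and miRNA, the score is the isoform usage shift summed
#' over the transcripts the miRNA targets:
#' `score = sum_t (p_IN(t) - p_CT(t)) * 1[site in t]`.
#' Scores lie in \[-1, 1\]: values near +1 mean the miRNA's target
#' isoforms are used much more after induction, values near -1 that they
#' are used more in the control, and 0 that usage of targeted isoforms
#' is unchanged — in particular, a miRNA targeting all or none of a
#' gene's transcripts always scores exactly 0, because usage changes sum
#' to zero within a gene.
#'
#' @param tab an `"isoform_usage"` table.
#' @param targets binary transcript x miRNA matrix; transcripts absent
#'   from it count as all-zero rows.
#' @param cond_ct,cond_in control and induced condition names.
#' @param genes optional subset of gene ids (default: all genes with
#'   defined proportions in both conditions).
#' @param cooperative if `TRUE`, the target matrix's values are used as
#'   site counts (cooperative binding); by default one-or-more sites
#'   collapse to presence/absence, the simple model.
#' @return Numeric gene x miRNA matrix of class `"usage_scores"`.
#' @examples
#' tab <- isoform_usage_table(
#'   data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
#'              fpkm_CT = c(10, 0), fpkm_IN = c(0, 10)))
#' targets <- matrix(c(0L, 1L), 2, 1,
#'                   dimnames = list(c("t1", "t2"), "miR-x"))
#' usage_scores(tab, targets)  # +1: full switch to the targeted isoform
#' @export
usage_scores <- function(tab, targets, cond_ct = "CT", cond_in = "IN",
                         genes = NULL, cooperative = FALSE) {
  stopifnot(inherits(tab, "isoform_usage"))
  if (!cooperative) targets <- pmin(targets, 1L)
  p_ct <- tab[[paste0("p_", cond_ct)]]
  p_in <- tab[[paste0("p_", cond_in)]]
  ok <- !is.na(p_ct) & !is.na(p_in)
  tab <- tab[ok, , drop = FALSE]
  delta <- (p_in - p_ct)[ok]
  tgt <- align_targets(targets, tab)
  if (is.null(genes)) genes <- sort(unique(tab$gene_id))
  gene_f <- factor(tab$gene_id, levels = genes)
  keep <- !is.na(gene_f)
  # score matrix = per-gene sum of delta-weighted target rows
  m <- rowsum(tgt[keep, , drop = FALSE] * delta[keep],
              group = gene_f[keep])
  # a constant site vector across a gene's isoforms carries no usage
  # information: its score is 0 by construction (exact, not rounded)
  ssum <- rowsum(tgt[keep, , drop = FALSE], group = gene_f[keep])
  ssq <- rowsum(tgt[keep, , drop = FALSE]^2, group = gene_f[keep])
  ksz <- as.vector(table(gene_f[keep]))[match(rownames(m),
                                              levels(gene_f))]
  m[ssq - ssum^2 / ksz == 0] <- 0
  out <- matrix(0, length(genes), ncol(targets),
                dimnames = list(genes, colnames(targets)))
  out[rownames(m), ] <- m
  structure(out, class = c("usage_scores", class(out)))
}

#' Count genes where small 3'UTR length differences change target sites
#'
#' For each length difference `d` of interest, counts the genes having
#' at least one transcript pair whose 3'UTR lengths differ by at most
#' `d` bases (and more than 0) while their miRNA target sets differ in
#' at least one miRNA — i.e. genes where a length change that small is
#' already enough to gain or lose a binding site.
#'
#' @param tab an `"isoform_usage"` table with `utr3_length` filled in.
#' @param targets binary transcript x miRNA matrix.
#' @param length_diffs positive integer differences of interest, in
#'   bases (default the shifts observed genome-wide: 20, 18, 12, 11).
#' @return Named integer vector: difference -> gene count. The total
#'   number of genes inspected (>= 2 annotated transcripts) is in
#'   `attr(x, "n_genes")`.
#' @export
site_gain_census <- function(tab, targets,
                             length_diffs = c(20L, 18L, 12L, 11L)) {
  stopifnot(inherits(tab, "isoform_usage"), all(length_diffs > 0))
  tab <- tab[!is.na(tab$utr3_length), , drop = FALSE]
  tgt <- align_targets(targets, tab)
  genes <- split(seq_len(nrow(tab)), tab$gene_id)
  genes <- genes[vapply(genes, length, 1L) >= 2L]
  counts <- stats::setNames(integer(length(length_diffs)),
                            as.character(length_diffs))
  for (idx in genes) {
    len <- tab$utr3_length[idx]
    rows <- tgt[idx, , drop = FALSE]
    pairs <- utils::combn(length(idx), 2L)
    dlen <- abs(len[pairs[1L, ]] - len[pairs[2L, ]])
    differs <- vapply(seq_len(ncol(pairs)), function(j) {
      any(rows[pairs[1L, j], ] != rows[pairs[2L, j], ])
    }, logical(1L))
    for (i in seq_along(length_diffs)) {
      d <- length_diffs[i]
      if (any(dlen > 0 & dlen <= d & differs))
        counts[i] <- counts[i] + 1L
    }
  }
  structure(counts, n_genes = length(genes))
}

#' Long-format view of a score matrix
#'
#' @param scores a `"usage_scores"` matrix.
#' @param drop_zero drop exact-zero scores (default TRUE; they carry no
#'   usage information).
#' @return data.frame with `gene_id`, `mirna_id`, `score`.
#' @export
scores_long <- function(scores, drop_zero = TRUE) {
  df <- data.frame(gene_id = rep(rownames(scores), times = ncol(scores)),
                   mirna_id = rep(colnames(scores), each = nrow(scores)),
                   score = as.vector(scores), stringsAsFactors = FALSE)
  if (drop_zero) df <- df[df$score != 0, , drop = FALSE]
  df <- df[order(df$gene_id, df$mirna_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
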