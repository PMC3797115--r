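#' Build an isoform usage table from per-transcript FPKM values
#'
#' The central container of the package: one row per transcript, with its
#' gene, optional 3'UTR length, FPKM per condition, and the within-gene
#' usage proportion per condition (FPKM divided by the gene's summed FPKM
#' in that condition). Genes whose total FPKM is zero in a condition have
#' undefined proportions there (`NA`) and are listed in
#' `attr(x, "undefined_genes")` so downstream tests can skip them.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   one `fpkm_<condition>` column per condition, and optionally
#'   `utr3_length` (integer bases).
#' @param conditions character vector of condition names, e.g.
#'   `c("CT", "IN")`. The corresponding `fpkm_<cond>` columns must exist.
#' @return A data.frame of class `"isoform_usage"` with added `p_<cond>`
#'   proportion columns and attributes `conditions`, `undefined_genes`
#'   (genes with zero total FPKM in at least one condition) and
#'   `n_excluded` (transcripts dropped by quality filtering upstream; 0
#'   when built directly).
#' @examples
#' tab <- isoform_usage_table(
#'   data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
#'              utr3_length = c(100L, 300L),
#'              fpkm_CT = c(3, 1), fpkm_IN = c(1, 3)),
#'   conditions = c("CT", "IN"))
#' tab$p_CT  # 0.75 0.25
#' @export
isoform_usage_table <- function(transcripts, conditions = c("CT", "IN")) {
  stopifnot(is.data.frame(transcripts))
  need <- c("transcript_id", "gene_id", paste0("fpkm_", conditions))
  miss <- setdiff(need, names(transcripts))
  if (length(miss) > 0L)
    stop("isoform table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(transcripts$transcript_id[
           duplicated(transcripts$transcript_id)]), collapse = ", "))
  for (cond in conditions) {
    fp <- transcripts[[paste0("fpkm_", cond)]]
    if (any(!is.finite(fp)) || any(fp < 0))
      stop("negative or non-finite FPKM values in condition ", cond)
  }
  if (!"utr3_length" %in% names(transcripts))
    transcripts$utr3_length <- NA_integer_
  if (any(transcripts$utr3_length < 0, na.rm = TRUE))
    stop("negative utr3_length")

  undefined <- character(0)
  for (cond in conditions) {
    fp <- transcripts[[paste0("fpkm_", cond)]]
    tot <- tapply(fp, transcripts$gene_id, sum)
    p <- fp / as.numeric(tot[transcripts$gene_id])
    p[as.numeric(tot[transcripts$gene_id]) == 0] <- NA_real_
    transcripts[[paste0("p_", cond)]] <- p
    undefined <- union(undefined, names(tot)[tot == 0])
  }
  rownames(transcripts) <- NULL
  structure(transcripts,
            conditions = conditions,
            undefined_genes = sort(undefined),
            n_excluded = attr(transcripts, "n_excluded") %||% 0L,
            class = c("isoform_usage", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cuffdiff-style fpkm_tracking table
#'
#' Parses the tab-separated `isoforms.fpkm_tracking` dialect: a header row
#' with a transcript id column (`tracking_id` or `transcript_id`), a
#' `gene_id` column, and per condition a `<cond>_FPKM` and a
#' `<cond>_status` column. Transcripts whose quantification status is not
#' `"OK"` in any requested condition are dropped (low-coverage FPKM
#' estimates are unreliable); the number dropped is recorded in the
#' `n_excluded` attribute and the ids in `excluded_ids`.
#'
#' @param path path to the TSV file. Lines starting with `#` are ignored.
#' @param conditions condition names to extract (default `c("CT","IN")`).
#' @return An `"isoform_usage"` table (see [isoform_usage_table()]).
#' @export
read_fpkm_tracking <- function(path, conditions = c("CT", "IN")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  id_col <- intersect(c("tracking_id", "transcript_id"), names(raw))[1]
  if (is.na(id_col))
    stop("fpkm_tracking file lacks a transcript id column ",
         "(tracking_id or transcript_id): ", path)
  if (!"gene_id" %in% names(raw))
    stop("fpkm_tracking file lacks required column gene_id: ", path)
  out <- data.frame(transcript_id = as.character(raw[[id_col]]),
                    gene_id = as.character(raw$gene_id),
                    stringsAsFactors = FALSE)
  if ("utr3_length" %in% names(raw))
    out$utr3_length <- as.integer(raw$utr3_length)
  keep <- rep(TRUE, nrow(out))
  for (cond in conditions) {
    fcol <- paste0(cond, "_FPKM"); scol <- paste0(cond, "_status")
    for (col in c(fcol, scol))
      if (!col %in% names(raw))
        stop("fpkm_tracking file lacks required column ", col, ": ", path)
    out[[paste0("fpkm_", cond)]] <- as.numeric(raw[[fcol]])
    keep <- keep & (raw[[scol]] == "OK")
  }
  excluded <- out$transcript_id[!keep]
  out <- out[keep, , drop = FALSE]
  tab <- isoform_usage_table(out, conditions)
  attr(tab, "n_excluded") <- length(excluded)
  attr(tab, "excluded_ids") <- excluded
  tab
}

#' Derive per-transcript 3'UTR lengths from a GTF/GFF annotation
#'
#' Sums the lengths of all `three_prime_utr` features of each transcript.
#' GTF coordinates are 1-based inclusive (Ensembl convention), so each
#' interval contributes `end - start + 1` bases. Transcripts with no
#' 3'UTR feature are absent from the returned map.
#'
#' @param path GTF/GFF file readable by [rtracklayer::import()].
#' @param feature_types feature `type` values treated as 3'UTR intervals.
#' @return Named integer vector: transcript_id -> total 3'UTR length in
#'   bases.
#' @export
utr3_lengths_from_gtf <- function(path,
                                  feature_types = c("three_prime_utr",
                                                    "three_prime_UTR")) {
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  if (!"transcript_id" %in% names(meta))
    stop("GTF has no transcript_id attribute: ", path)
  sel <- as.character(meta$type) %in% feature_types
  gr <- gr[sel]
  if (length(gr) == 0L)
    return(stats::setNames(integer(0), character(0)))
  widths <- BiocGenerics::width(gr)  # end - start + 1 on 1-based intervals
  if (any(widths < 1L)) stop("3'UTR interval with non-positive width in ", path)
  tx <- as.character(S4Vectors::mcols(gr)$transcript_id)
  len <- tapply(widths, tx, sum)
  stats::setNames(as.integer(len), names(len))
}

#' Read a precomputed transcript -> 3'UTR length TSV
#'
#' Two-column table (`transcript_id`, `utr3_length`); the alternative to
#' deriving lengths from a GTF.
#'
#' @param path TSV path; `#` comment lines ignored.
#' @return Named integer vector transcript_id -> length.
#' @export
read_utr3_lengths <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  for (col in c("transcript_id", "utr3_length"))
    if (!col %in% names(df)) stop("missing required column ", col, ": ", path)
  if (any(df$utr3_length < 0)) stop("negative utr3_length in ", path)
  stats::setNames(as.integer(df$utr3_length), df$transcript_id)
}

#' Attach 3'UTR lengths to an isoform usage table
#'
#' @param tab an `"isoform_usage"` table.
#' @param lengths named vector transcript_id -> length (from
#'   [utr3_lengths_from_gtf()] or [read_utr3_lengths()]). Transcripts not
#'   in the map get `NA` and are excluded from length-based analyses.
#' @return The table with its `utr3_length` column filled in.
#' @export
set_utr3_lengths <- function(tab, lengths) {
  stopifnot(inherits(tab, "isoform_usage"))
  tab$utr3_length <- as.integer(unname(lengths[tab$transcript_id]))
  tab
}

#' Gene-level mRNA log2 fold change from summed FPKM
#'
#' Sums the retained transcripts' FPKM per gene in each condition and
#' forms `log2((sum_num + pc) / (sum_den + pc))`. The pseudocount guards
#' against zero totals.
#'
#' @param tab an `"isoform_usage"` table.
#' @param cond_num,cond_den numerator (induced) and denominator (control)
#'   condition names.
#' @param pseudocount positive FPKM offset, default 0.1.
#' @return Named numeric vector gene_id -> log2 fold change.
#' @examples
#' tab <- isoform_usage_table(
#'   data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
#'              fpkm_CT = c(1, 1), fpkm_IN = c(4, 4)))
#' gene_logfc(tab)  # log2(8.1/2.1)
#' @export
gene_logfc <- function(tab, cond_num = "IN", cond_den = "CT",
                       pseudocount = 0.1) {
  stopifnot(inherits(tab, "isoform_usage"))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  for (cond in c(cond_num, cond_den))
    if (!cond %in% attr(tab, "conditions"))
      stop("unknown condition: ", cond)
  num <- tapply(tab[[paste0("fpkm_", cond_num)]], tab$gene_id, sum)
  den <- tapply(tab[[paste0("fpkm_", cond_den)]], tab$gene_id, sum)
  lfc <- log2((num + pseudocount) / (den + pseudocount))
  stats::setNames(as.numeric(lfc), names(lfc))
}

#' Read a protein log fold-change table
#'
#' Expects columns `gene_symbol`, `logfc_day1`, `logfc_day3`,
#' `logfc_day5`, `logfc_day7` and `set_label` (`secreted` or `nuclear`),
#' the shape of SILAC-style differentiation time courses.
#'
#' @param path TSV path; `#` comment lines ignored.
#' @return data.frame with those columns, class `"protein_fc"`.
#' @export
read_protein_fc <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene_symbol", paste0("logfc_day", c(1, 3, 5, 7)), "set_label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("protein table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$set_label), c("secreted", "nuclear"))
  if (length(bad) > 0L)
    stop("unknown set_label value(s): ", paste(bad, collapse = ", "))
  class(df) <- c("protein_fc", "data.frame")
  df
}

#' Join protein rows to expression genes by case-insensitive symbol
#'
#' Cross-species comparisons (murine protein sets against human
#' expression) are joined on upper-cased gene symbols only; anything more
#' elaborate (ortholog inference) is out of scope. Unmatched protein rows
#' are reported, never silently dropped; duplicate symbols are all joined
#' with a warning.
#'
#' @param prot a `"protein_fc"` data.frame.
#' @param genes character vector of gene symbols present in the
#'   expression data.
#' @return list with `matched` (protein rows plus a `matched_gene`
#'   column) and `unmatched` (character vector of symbols not found).
#' @export
match_protein_genes <- function(prot, genes) {
  stopifnot(is.data.frame(prot), "gene_symbol" %in% names(prot))
  key <- toupper(prot$gene_symbol)
  lut <- stats::setNames(genes, toupper(genes))
  if (anyDuplicated(key))
    warning("duplicate gene symbols in protein table: ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  hit <- key %in% names(lut)
  matched <- prot[hit, , drop = FALSE]
  matched$matched_gene <- unname(lut[key[hit]])
  list(matched = matched,
       unmatched = sort(unique(prot$gene_symbol[!hit])))
}

#' Read a binary transcript x miRNA target matrix
#'
#' Accepts either the long format (columns `transcript_id`, `mirna_id`;
#' each row asserts at least one seed site) or a wide 0/1 matrix whose
#' first column is `transcript_id`. Multiplicity is never recorded: one
#' or more sites collapse to 1.
#'
#' @param path TSV path.
#' @param transcripts optional transcript universe; absent transcripts
#'   get all-zero rows so usage vectors and target rows stay aligned.
#' @return Integer 0/1 matrix, rownames transcript ids, colnames miRNA ids.
#' @export
read_mirna_targets <- function(path, transcripts = NULL) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("transcript_id", "mirna_id") %in% names(df))) {
    tx <- unique(c(df$transcript_id, transcripts))
    mi <- sort(unique(df$mirna_id))
    mat <- matrix(0L, length(tx), length(mi), dimnames = list(tx, mi))
    mat[cbind(match(df$transcript_id, tx), match(df$mirna_id, mi))] <- 1L
  } else if ("transcript_id" %in% names(df)) {
    tx <- df$transcript_id
    mat <- as.matrix(df[, setdiff(names(df), "transcript_id"), drop = FALSE])
    if (!all(mat %in% c(0, 1)))
      stop("wide target matrix must be strictly binary: ", path)
    storage.mode(mat) <- "integer"
    rownames(mat) <- tx
    if (!is.null(transcripts)) {
      extra <- setdiff(transcripts, tx)
      if (length(extra) > 0L) {
        pad <- matrix(0L, length(extra), ncol(mat),
                      dimnames = list(extra, colnames(mat)))
        mat <- rbind(mat, pad)
      }
    }
  } else {
    stop("target table needs transcript_id (+ mirna_id for long format): ",
         path)
  }
  mat
}

#' Align a target matrix to an isoform table's transcripts
#'
#' @param targets binary matrix from [read_mirna_targets()].
#' @param tab an `"isoform_usage"` table.
#' @return 0/1 matrix with one row per transcript of `tab`, in table
#'   order; transcripts missing from `targets` become all-zero rows.
#' @export
align_targets <- function(targets, tab) {
  stopifnot(inherits(tab, "isoform_usage"))
  tx <- tab$transcript_id
  out <- matrix(0L, length(tx), ncol(targets),
                dimnames = list(tx, colnames(targets)))
  hit <- intersect(tx, rownames(targets))
  out[hit, ] <- targets[hit, , drop = FALSE]
  out
}

# ---- writers -------------------------------------------------------------

#' Write a data frame as TSV with a provenance header comment
#'
#' All writers emit a single `#` comment line recording the tool version
#' and the parameters used, then a tab-separated table. Deterministic:
#' no timestamps, so identical inputs give byte-identical files.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list of parameters echoed into the header.
#' @return `path`, invisibly.
#' @export
write_tsv_header <- function(df, path, params = list()) {
  pv <- as.character(utils::packageVersion("apaswitch"))
  ptxt <- if (length(params) == 0L) "" else
    paste0("; ", paste(names(params), unlist(lapply(params, format)),
                       sep = "=", collapse = ", "))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# apaswitch ", pv, ptxt), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an isoform usage table in the fpkm_tracking dialect
#'
#' Emits `tracking_id`, `gene_id`, `utr3_length`, and per condition
#' `<cond>_FPKM` / `<cond>_status` (all retained rows are `OK`), so that
#' [read_fpkm_tracking()] round-trips the table.
#'
#' @param tab an `"isoform_usage"` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_tracking <- function(tab, path) {
  stopifnot(inherits(tab, "isoform_usage"))
  conds <- attr(tab, "conditions")
  out <- data.frame(tracking_id = tab$transcript_id,
                    gene_id = tab$gene_id,
                    utr3_length = tab$utr3_length,
                    stringsAsFactors = FALSE)
  for (cond in conds) {
    out[[paste0(cond, "_FPKM")]] <- format(tab[[paste0("fpkm_", cond)]],
                                           digits = 15, trim = TRUE,
                                           scientific = FALSE)
    out[[paste0(cond, "_status")]] <- "OK"
  }
  write_tsv_header(out, path,
                   params = list(conditions = paste(conds, collapse = "/")))
}
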