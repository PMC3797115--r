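#' Run the full APA analysis pipeline and write a manifest
#'
#' Executes every stage in dependency order on one dataset — trend
#' testing, miRNA usage scoring, the site-gain census, protein model
#' search, the permutation bootstrap, miRNA co-occurrence, and gene-set
#' ranking — writing one TSV per stage into `outdir`, then a manifest
#' listing every output with its MD5 content hash, the parameters, and
#' the seed. A failure in any stage aborts before later stages run; the
#' manifest is written last, so its presence certifies a complete run.
#'
#' @param isoforms an `"isoform_usage"` table, or a path to an
#'   fpkm_tracking TSV.
#' @param targets binary transcript x miRNA matrix, or a path readable
#'   by [read_mirna_targets()].
#' @param protein a `"protein_fc"` data.frame, or a path readable by
#'   [read_protein_fc()]. `NULL` skips the model and bootstrap stages'
#'   content (their files record the skip).
#' @param gene_set character vector of gene ids, or a path (one id per
#'   line); `NULL` ranks against an empty report.
#' @param outdir output directory (created).
#' @param utr3 optional named length vector, GTF path, or length-TSV
#'   path used to fill in `utr3_length` when the isoform table lacks it.
#' @param day protein time point modelled (default 3, the induction day
#'   matched by the mRNA contrast).
#' @param protein_set restrict to one `set_label` (default: all rows).
#' @param cond_ct,cond_in condition names.
#' @param pseudocount,count_scale,length_diffs,search,max_size,fdr
#'   stage parameters, passed through.
#' @param n_perm,win_threshold,seed bootstrap parameters.
#' @param weight_condition,min_rows co-occurrence parameters.
#' @param min_genes minimum complete rows for model fitting.
#' @param mirnas_cooccur optional cap on the number of miRNA columns
#'   entering the all-pairs co-occurrence stage (the most frequently
#'   targeting ones are kept); `NULL` uses all.
#' @return list of class `"run_manifest"`: `outputs` (named paths),
#'   `hashes`, `parameters`, `seed`, `manifest_path`.
#' @export
run_all <- function(isoforms, targets, protein = NULL, gene_set = NULL,
                    outdir, utr3 = NULL,
                    day = 3, protein_set = NULL,
                    cond_ct = "CT", cond_in = "IN",
                    pseudocount = 0.1, count_scale = 1,
                    length_diffs = c(20L, 18L, 12L, 11L),
                    search = "exhaustive_within_significant",
                    max_size = 5L, fdr = 0.05,
                    n_perm = 1000L, win_threshold = 0.95, seed = 1L,
                    weight_condition = "IN", min_rows = 3L,
                    min_genes = 10L, mirnas_cooccur = NULL) {
  # resolve inputs up front: a missing file must fail before any stage
  for (p in list(isoforms, targets, protein, gene_set, utr3)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop("input file not found: ", p)
  }
  if (is.character(isoforms))
    isoforms <- read_fpkm_tracking(isoforms, c(cond_ct, cond_in))
  if (is.character(targets))
    targets <- read_mirna_targets(targets,
                                  transcripts = isoforms$transcript_id)
  if (is.character(protein)) protein <- read_protein_fc(protein)
  if (!is.null(gene_set) && is.character(gene_set) &&
      length(gene_set) == 1L && file.exists(gene_set))
    gene_set <- read_gene_set(gene_set)
  if (!is.null(utr3)) {
    if (is.character(utr3) && length(utr3) == 1L)
      utr3 <- if (grepl("\\.g[tf]f3?(\\.gz)?$", utr3, ignore.case = TRUE))
        utr3_lengths_from_gtf(utr3) else read_utr3_lengths(utr3)
    isoforms <- set_utr3_lengths(isoforms, utr3)
  }
  if (all(is.na(isoforms$utr3_length)))
    stop("isoform table has no 3'UTR lengths; supply utr3")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- list(day = day, cond_ct = cond_ct, cond_in = cond_in,
                 pseudocount = pseudocount, count_scale = count_scale,
                 search = search, max_size = max_size, fdr = fdr,
                 n_perm = n_perm, win_threshold = win_threshold,
                 seed = seed, weight_condition = weight_condition,
                 min_rows = min_rows, min_genes = min_genes)
  outputs <- character(0)
  emit <- function(name, df, extra = list()) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    write_tsv_header(df, path, params = c(list(stage = name), extra))
    outputs[[name]] <<- path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  trend <- stage("trend", apa_trend(isoforms, cond_ct, cond_in,
                                    count_scale = count_scale))
  emit("trend", as.data.frame(trend))

  scores <- stage("score", usage_scores(isoforms, targets,
                                        cond_ct, cond_in))
  emit("scores", scores_long(scores))

  census <- stage("census", site_gain_census(isoforms, targets,
                                             length_diffs))
  emit("census", data.frame(length_diff = as.integer(names(census)),
                            n_genes = as.integer(census)),
       extra = list(n_genes_inspected = attr(census, "n_genes")))

  if (!is.null(protein)) {
    stage("model", {
      if (!is.null(protein_set))
        protein <- protein[protein$set_label %in% protein_set, ,
                           drop = FALSE]
      lfc <- gene_logfc(isoforms, cond_in, cond_ct, pseudocount)
      joined <- match_protein_genes(protein, names(lfc))$matched
      y <- joined[[paste0("logfc_day", day)]]
      x <- unname(lfc[joined$matched_gene])
      sc <- scores[joined$matched_gene, , drop = FALSE]
      rownames(sc) <- joined$matched_gene
      names(y) <- joined$matched_gene
      sr <- search_models(y, x, sc, strategy = search,
                          max_size = max_size, fdr = fdr,
                          min_genes = min_genes)
      mdl <- data.frame(
        rank = seq_along(sr$models),
        predictors = vapply(sr$models, function(m)
          paste(m$predictors, collapse = "+"), character(1)),
        bic = vapply(sr$models, `[[`, numeric(1), "bic"),
        r_squared = vapply(sr$models, `[[`, numeric(1), "r_squared"),
        n_genes = vapply(sr$models, `[[`, integer(1), "n_genes"))
      emit("models", mdl)
      bt <- bootstrap_mirna(y, x, sc, n_perm = n_perm, seed = seed,
                            win_threshold = win_threshold)
      emit("bootstrap", bt$results,
           extra = list(seed = seed,
                        kruskal_p = signif(bt$kruskal_p, 6)))
    })
  } else {
    emit("models", data.frame(note = "no protein table supplied"))
    emit("bootstrap", data.frame(note = "no protein table supplied"))
  }

  cooc_targets <- targets
  if (!is.null(mirnas_cooccur) && ncol(targets) > mirnas_cooccur) {
    keep <- names(sort(colSums(targets), decreasing = TRUE))[
      seq_len(mirnas_cooccur)]
    cooc_targets <- targets[, sort(keep), drop = FALSE]
  }
  cooc <- stage("cooccur",
                cooccurrence_pairs(cooc_targets, isoforms,
                                   weight_condition, min_rows))
  emit("cooccur", cooc)

  rk <- if (!is.null(gene_set))
    stage("rank", rank_gene_set(trend, gene_set)) else NULL
  if (!is.null(rk)) {
    emit("rank", rk$ranks,
         extra = list(enrichment_p = signif(rk$enrichment_p, 6),
                      n_negative = rk$counts[["n_negative"]],
                      n_zero = rk$counts[["n_zero"]],
                      n_positive = rk$counts[["n_positive"]]))
  } else {
    emit("rank", data.frame(note = "no gene set supplied"))
  }

  hashes <- tools::md5sum(unlist(outputs))
  names(hashes) <- basename(names(hashes))
  manifest <- data.frame(file = basename(unlist(outputs)),
                         md5 = unname(hashes),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(outdir, "manifest.tsv")
  write_tsv_header(manifest, manifest_path, params = params)
  structure(list(outputs = outputs, hashes = hashes,
                 parameters = params, seed = seed,
                 manifest_path = manifest_path),
            class = "run_manifest")
}
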