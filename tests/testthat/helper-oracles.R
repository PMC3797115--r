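# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they share no
# code path with the package implementation.

# CMH linear-trend statistic by literal expansion of the 2 x k count
# table into one unit record per count, then cor() over the records.
cmh_expansion_oracle <- function(counts_ct, counts_in, lengths) {
  u <- c(rep(0, sum(counts_ct)), rep(1, sum(counts_in)))
  v <- c(rep(lengths, times = counts_ct), rep(lengths, times = counts_in))
  r <- suppressWarnings(stats::cor(u, v))
  n <- length(u)
  list(trend_r = r, cmh_stat = (n - 1) * r^2, n = n)
}

# 3'UTR length by counting individual bases of 1-based inclusive
# intervals, duplicates collapsed per interval occurrence (additive).
utr3_bases_oracle <- function(starts, ends) {
  sum(vapply(seq_along(starts),
             function(i) length(seq(starts[i], ends[i])), numeric(1)))
}

# Random 2 x k count table with total n <= n_max and k transcripts.
random_count_table <- function(k = sample(2:5, 1), n_max = 200) {
  n <- sample(2:n_max, 1)
  n_ct <- sample(1:(n - 1), 1)
  lengths <- sort(sample(50:3000, k))
  list(counts_ct = as.vector(stats::rmultinom(1, n_ct, rep(1, k))),
       counts_in = as.vector(stats::rmultinom(1, n - n_ct, rep(1, k))),
       lengths = lengths)
}

# Random single-gene usage table with defined proportions.
random_gene_usage <- function(k = sample(2:6, 1), gene = "g") {
  p_ct <- stats::rgamma(k, 1); p_ct <- p_ct / sum(p_ct)
  p_in <- stats::rgamma(k, 1); p_in <- p_in / sum(p_in)
  list(lengths = sample(50:3000, k), p_ct = p_ct, p_in = p_in)
}

# Minimal Ensembl-dialect GTF writer for fixture generation.
write_gtf <- function(path, df) {
  # df: seqname, type, start, end, transcript_id
  lines <- sprintf(
    '%s\ttest\t%s\t%d\t%d\t.\t+\t.\tgene_id "g"; transcript_id "%s";',
    df$seqname, df$type, df$start, df$end, df$transcript_id)
  writeLines(lines, path)
  path
}

# Small isoform table builder used by several files.
make_usage_tab <- function(lengths, fpkm_ct, fpkm_in,
                           gene = "g1", tx_prefix = "t") {
  apaswitch::isoform_usage_table(data.frame(
    transcript_id = paste0(tx_prefix, seq_along(lengths)),
    gene_id = gene, utr3_length = as.integer(lengths),
    fpkm_CT = fpkm_ct, fpkm_IN = fpkm_in,
    stringsAsFactors = FALSE))
}
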