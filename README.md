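# apaswitch

Alternative polyadenylation (APA) generates transcript isoforms of the same gene
that differ in 3′UTR length, and with it in the miRNA binding sites they carry.
During cellular differentiation the balance of isoform usage can shift towards
longer or shorter 3′UTRs, changing how strongly a gene is exposed to miRNA
repression — one reason protein fold-changes often track mRNA fold-changes so
poorly. `apaswitch` is an R package for quantifying this mechanism from
isoform-level RNA-seq abundance tables (cuffdiff-style `fpkm_tracking` files)
in a two-condition design (control vs induced), aimed at transcriptomics
analysts studying differentiation systems.

## What it computes

For each gene with isoform usage proportions `p_CT(t)`, `p_IN(t)` over its
transcripts `t` with 3′UTR lengths `len(t)`:

- **Usage-weighted 3′UTR shift** — `Δ = Σ_t len(t)·(p_IN(t) − p_CT(t))`,
  positive when longer 3′UTRs are favoured after induction; global means with
  and without >1 kb outliers, and a one-sample Wilcoxon test of the genome-wide
  shift.
- **Linear-trend test** — the gene's 2×k count table (conditions × transcripts,
  columns scored by 3′UTR length) is tested with the Cochran–Mantel–Haenszel
  statistic `M² = (n−1)·r²`, where `r` is the count-weighted Pearson correlation
  of condition and length; χ²₁ p-values, BH-adjusted.
- **miRNA usage scores** — for each gene and miRNA,
  `score = Σ_t (p_IN(t) − p_CT(t))·1[site in t]` ∈ [−1, 1]: +1 means a complete
  switch towards the miRNA's target isoforms after induction.
- **miRNA-augmented protein models** — OLS fits
  `logFC_prot ~ logFC_mRNA + Σ_i score(miR_i)` selected by BIC (univariate scan,
  then exhaustive combinations of the FDR-significant miRNAs up to size 5, or
  greedy forward search), with a permutation bootstrap of explained variance per
  miRNA and a Kruskal–Wallis comparison of high- vs low-win miRNAs. The base
  slope estimates the range-compression exponent `b` of protein on mRNA
  quantity.
- **Site-gain census, co-occurrence, gene-set ranking** — genes where transcript
  pairs within 20/18/12/11 bases of 3′UTR length already differ in target sites;
  pairwise miRNA Pearson correlations on the presence/absence matrix and its
  usage-weighted counterpart after pairwise-zero filtering; and the position of
  a gene set (e.g. PluriNet) within the genome-wide ranking of 3′UTR shifts.
- **Synthetic data** — `simulate_apa()` generates isoform tables, target
  matrices and protein fold-changes with known planted structure for all of the
  above, and `worked_toy()` is a five-gene hand-auditable fixture.

## Worked example

```r
library(apaswitch)

toy <- worked_toy()
tr  <- apa_trend(toy$isoforms)
tr[, c("gene_id", "delta_len", "trend_r", "cmh_stat", "p_value")]
#>   gene_id delta_len   trend_r cmh_stat      p_value
#> 1      G1      60.0  0.340503 34.66667 3.912743e-09
#> 2      G2     200.0  1.000000 19.00000 1.307185e-05
#> 3      G3       0.0  0.000000  0.00000 1.000000e+00
#> 4      G4      -5.5 -0.489116 35.64593 2.366414e-09
```

G2 switches completely from a 100-base to a 300-base 3′UTR isoform: its usage
shift is +200 bases, the trend correlation is exactly 1 and the CMH statistic
equals `(20−1)·1² = 19` on its 20 observation-equivalents. G4 shifts towards
its *shorter* isoform (negative trend), and G3's unchanged usage gives the null
result `r = 0, p = 1`.

```r
usage_scores(toy$isoforms, toy$targets)["G2", ]
#> miR-a miR-b miR-c
#>     0     1     0
```

miR-b targets only G2's long isoform, so its usage score is +1 — maximal gain
of exposure after induction; miR-a targets no G2 isoform and scores 0.

```r
sc  <- usage_scores(toy$isoforms, toy$targets)
lfc <- gene_logfc(toy$isoforms)
y   <- setNames(toy$protein$logfc_day3, toy$protein$gene_symbol)
sr  <- search_models(y, unname(lfc[names(y)]), sc[names(y), ], min_genes = 3)
sr$models[[1]]
#> APA protein fold-change model (5 genes)
#>   predictors: logfc_mrna + miR-c
#>   R^2 = 0.9995, BIC = -26.34
#> (Intercept)  logfc_mrna       miR-c
#>      0.1080      0.4941     -1.9756
```

The BIC search recovers the planted model: protein fold-change is explained by
mRNA fold-change (slope ≈ 0.5, the planted compression) plus repression by
miR-c (coefficient ≈ −2, the planted per-site effect).

`run_all()` executes every stage on one dataset and writes seven TSVs plus a
hash manifest into an output directory.

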