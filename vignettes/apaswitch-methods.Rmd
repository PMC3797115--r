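---
title: "Methods: quantifying APA isoform switching and its miRNA consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying APA isoform switching and its miRNA consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apaswitch)
```

## The problem

Alternative polyadenylation produces isoforms of one gene that differ only in
3′UTR length. Because miRNA binding sites live in the 3′UTR, a shift in isoform
usage between two cellular states — here called CT (control) and IN (induced),
the design of a differentiation time course — changes a gene's exposure to
miRNA repression without changing its coding sequence. `apaswitch` measures
that shift per gene, tests it, propagates it into a per-miRNA exposure score,
and asks how much of the mismatch between protein and mRNA fold-changes the
scores explain.

The package consumes isoform-level abundances (FPKM) as produced by
cuffdiff-style quantification; read mapping and transcript assembly are
upstream and out of scope, as are miRNA expression levels — only the presence
of target sites on isoforms is modelled.

## Usage proportions and the length shift

Within each gene and condition, isoform usage is the transcript's FPKM divided
by the gene's summed FPKM. Transcripts whose quantification status is not `OK`
in *any* analysed condition are dropped first (the strictest reading of
quality filtering: a low-coverage FPKM in either condition contaminates both
proportions). Genes with zero total FPKM in a condition have undefined
proportions and are excluded from all usage-based analyses, with the exclusion
recorded.

The per-gene summary is the usage-weighted 3′UTR length difference
$\Delta = \sum_t \mathrm{len}(t)\,\bigl(p_{IN}(t) - p_{CT}(t)\bigr)$,
equivalently the difference of usage-weighted mean lengths. Since usage changes
sum to zero within a gene, $\Delta$ is invariant to adding a constant to all of
a gene's lengths — only *relative* isoform lengths matter. Global summaries
report the mean $\Delta$ with and without outliers (|Δ| > 1 kb by default;
a handful of extreme 3′UTRs otherwise dominate the mean), and a one-sample
Wilcoxon signed-rank test of the per-gene trend statistic against zero. The
signed-rank variant against zero is a deliberate choice over comparing the
positive and negative subsets; both views are available from the trend table.

## The linear-trend test

Each gene is cast as a 2×k contingency table: rows CT/IN (scored 0/1), columns
its transcripts scored by 3′UTR length, cells condition-specific counts. With
an ordered quantitative column score, the Cochran–Mantel–Haenszel linear-trend
statistic $M^2 = (n-1)r^2$ — $r$ the count-weighted Pearson correlation of row
and column scores, $n$ the table total — is more sensitive than a general
independence χ² whenever usage changes monotonically along length, which is
exactly the APA alternative. $M^2$ is referred to χ² with 1 df; positive $r$
means longer 3′UTRs associate with induction. The implementation computes $r$
in closed form from the counts; the test suite checks it against a literal
expansion into unit records on hundreds of random tables.

Counts are FPKM values rounded to the nearest integer (floored at zero),
optionally multiplied by a `count_scale` before rounding. FPKM is a normalized
abundance, not a read count, and the statistic's magnitude — unlike $r$ —
grows with the assumed total $n$; the rounding rule makes the choice explicit
and reproducible, and `count_scale` lets users emulate deeper sampling. Genes
need at least two transcripts with annotated 3′UTRs, defined proportions in
both conditions, nonzero counts in both rows, and length variance in the
columns; anything else is skipped with a recorded reason. Multiple testing is
Benjamini–Hochberg (the procedure behind every FDR threshold in the package).

## miRNA usage scores

For gene $g$ and miRNA $i$ the score is
$S_{gi} = \sum_t \bigl(p_{IN}(t)-p_{CT}(t)\bigr)\,\mathbb{1}[\text{site of } i
\text{ in } t]$, bounded by the total-variation distance between the usage
vectors and hence by 1. A miRNA targeting all or none of a gene's isoforms is
structurally uninformative and scores exactly 0 — enforced algebraically, not
by rounding. One-or-more sites collapse to presence (`cooperative = FALSE`,
the default); site counts can be used instead, but the simple model is the
primary one. 3′UTR lengths come from an Ensembl-dialect GTF
(`three_prime_utr` features, 1-based inclusive coordinates, intervals summed
per transcript) or a precomputed length table.

The site-gain census asks whether length differences as small as the observed
genome-wide shifts can change targeting: for each probed difference $d$
(defaults 20, 18, 12, 11 bases) it counts genes with at least one transcript
pair at $0 < |\Delta \mathrm{len}| \le d$ whose target sets differ. The bound
is interpreted as "at most $d$" — the question is whether differences *that
small* already matter; an exact-difference variant would depend on annotation
granularity.

## Protein fold-change models

The base model regresses protein log fold-change on mRNA log fold-change
(genes joined across species by case-insensitive symbol only). If absolute
protein scales as a power of mRNA quantity, $P = c\,M^b$ — translational
efficiency decaying with expression — then log fold-changes satisfy
$\mathrm{logFC}_{prot} = b\,\mathrm{logFC}_{mRNA}$ exactly, so the fitted
slope estimates the compression exponent $b$ and the relation is noiselessly
recoverable (a property the tests verify to 1e-6). Likewise, a per-target-site
exponential decay of mRNA multiplies fold-changes by $e^{-\gamma S}$, which on
the log scale is precisely a linear term in the usage score; the miRNA
coefficients therefore estimate repression strengths $\gamma_i$.

Model selection fits each miRNA univariately (base + one score column),
BH-adjusts the score-coefficient p-values, then explores combinations of two
to five miRNAs. Exhausting all subsets of several hundred miRNAs is
combinatorially infeasible, so the exhaustive search is restricted to the
univariate-significant set (FDR < 0.05 by default), with a greedy
forward-by-BIC alternative over all miRNAs. Because scores of different
miRNAs on the same gene all derive from one usage-shift vector, they are
strongly correlated and the significant set can be large; the exhaustive
stage therefore scores every subset with a fast least-squares BIC and
refits only the 50 best as full models. BIC is computed from the Gaussian
log-likelihood with penalty $(k+1)\ln n$ counting intercept, slopes and the
error variance — fixed so rankings are bit-reproducible (it coincides with
`stats::BIC` for `lm`, which a test asserts). Models are returned in ascending
BIC order. Degenerate inputs fail loudly: constant score columns are rejected
by name, exactly collinear pairs are named, and fits require a minimum number
of complete gene rows (default 10).

The permutation bootstrap guards against score-matrix sampling artifacts: per
miRNA, its score values are randomly reassigned to genes `n_perm` times
(default 1000, minimum 100; the permutation preserves the score multiset by
construction) and the fraction of permutations the true model's $R^2$ beats is
the win fraction. Signal miRNAs win essentially always; under the null the win
fraction is uniform. miRNAs are split at a win threshold (default 0.95) and
the explained variances of the two groups compared by Kruskal–Wallis. Both
numbers are configuration, never hard-coded. A single integer seed drives the
whole procedure.

## Co-occurrence and its interpretation caveat

Pairwise miRNA correlations are computed on the transcript × miRNA
presence/absence matrix and on its usage-weighted counterpart (each row
multiplied by the transcript's usage proportion in a chosen condition — IN by
default, with CT and the usage shift as alternatives, since weighting by
"the proportion used" is condition-ambiguous). For each pair, rows where
*neither* miRNA is present are removed first; most transcripts carry neither
of any given pair, and those rows carry no co-occurrence information. The same
presence-based filter is applied to both matrix flavours, so with unit weights
the weighted correlation reduces to the binary one exactly. Pearson
correlation (matching the method's framing) with t-distribution p-values on
$n-2$ df; pairs with fewer than `min_rows` survivors or a constant column are
flagged not-computable, except that columns identical on every surviving row
are defined as perfect co-occurrence ($r = 1$) — under presence filtering an
identical pair is constant 1 on the surviving rows and plain Pearson would be
undefined there.

Two consequences of the filter deserve emphasis. Conditioning on "at least one
present" induces *negative* correlation between truly independent miRNAs
(about −1/3 at presence probability 1/2, and strongly "significant" at
realistic n) — the test suite measures this deliberately. Binary and weighted
correlations should therefore be compared *against each other*, which is how
the method uses them, not against an independence null.

## Gene-set ranking

Genes are sorted ascending by $\Delta$ (rank 1 = strongest shortening; ties
broken by gene id, making the ranking a deterministic permutation) and a gene
set is located within the ranking: member ranks, the cumulative fraction of
members along the ranking (diagonal = distributed like all genes), and the
negative/zero/positive split of member $\Delta$s (|Δ| < 1e-9 bases counts as
zero). The original method reads the density and cumulative curves by eye; a
two-sided Mann–Whitney test of member vs non-member $\Delta$ is added here as
a quantitative surrogate and should be read as an extension. When the set
covers the whole ranked universe there is no complement to compare against and
the p-value is `NA`.

## The synthetic generator

`simulate_apa()` emulates the data structure the analysis assumes, at the
scale of the motivating study type: 2,000 genes with 1–5 isoforms each,
log-normal 3′UTR lengths (median 800 bases), 400 miRNAs, 150 protein-measured
genes (the order of a SILAC secretome panel). Control usage is Dirichlet
(concentration 1.5); multi-isoform genes tilt their induced usage along the
length ranking by $p_{IN} \propto p_{CT}\,e^{d\,s\,z}$ with $z$ the centred
length rank in [−1, 1], $s$ the shift magnitude (default 1.5, a modest shift;
≈6 produces near-complete switches) and planted direction $d$ positive with
probability 0.6 by default — a modest, consistent lengthening bias. Gene
totals are log-normal with a log-normal fold change; transcript FPKM adds
multiplicative measurement noise (sdlog 0.05). Site presence is Bernoulli with
probability proportional to 3′UTR length (4e-5 per base), so longer isoforms
stochastically carry more sites. Protein log fold-changes follow
$\beta_0 + b\,\mathrm{logFC}_{mRNA} - \sum_i \gamma_i S_i + \varepsilon$ with
defaults $b = 0.2$, one planted repressive miRNA with $\gamma = 2$, and noise
SD 0.1; days 1/5/7 scale the systematic part by day/3 around the matched
day-3 contrast. The generated relation uses the *realized* mRNA fold-changes
and scores, so the modelled assumption is literally true in the emitted data —
which is what makes parameter recovery a valid correctness check, and also
what it limits: passing recovery shows the estimators work when the model
holds, not that real protein responses are linear in usage scores, free of
confounded miRNA expression changes, or measured without the cross-species
and cross-platform noise of real proteomics. Quality-status failures,
replicate structure and annotation errors are likewise not emulated.

`worked_toy()` is the five-gene, three-miRNA hand-auditable counterpart with
nested target sets on increasing lengths; every number it produces is checked
against hand computation in the tests, and the full pipeline's outputs on it
are shipped as byte-exact regression fixtures.

## Numerical choices and problem sizes

Proportions are validated to sum to 1 within 1e-9; exact-zero conservation of
scores is structural; CMH agreement with the expansion oracle is asserted to
1e-9; the noiseless compression slope to 1e-6. Ties in the gene ranking break
by id; trend classes use the strict sign of $r$ (exactly 0 = "none"). The
test suite runs its heaviest checks at 500 random CMH tables, 1,000 random
genes for score properties, 20 simulated studies at the default scale for
slope/selection recovery, and 10×50 null miRNAs × 200 permutations for
bootstrap calibration — sizes chosen to make the statistical assertions
stable across seeds while keeping a full run in a few minutes.

## Known limitations

Pooled two-condition comparison only (no replicate-stratified CMH); gene-level
mRNA fold-change is a pseudocounted FPKM-sum ratio, a deliberate simplification
of count-model differential expression; cross-species joining is
case-insensitive symbol equality, nothing more; target tables are consumed as
given (no seed matching); and the co-occurrence correlations inherit the
filter-induced dependence described above.
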