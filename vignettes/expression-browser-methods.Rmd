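---
title: "Statistical methods behind the expression browser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind the expression browser}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprbrowser)
```

## The data model

`exprbrowser` assumes expression has already been quantified and normalized
upstream (FPKM, TPM, normalized counts — any non-negative per-gene value).
Its unit of input is a wide table: one row per gene, one column per
replicate, column names `<GROUP><replicate>` where the group label is a
digit-free sample name and the trailing integer (the maximal trailing digit
run) is the replicate index. Every group needs at least two replicates,
because everything downstream — SEM, ANOVA, Welch tests — is built on
within-group variance. Empty cells are treated as missing observations and
excluded from that gene/group's `n`; if fewer than two observations remain,
the gene/group is flagged rather than silently dropped.

Annotations arrive as a long table, one row per (gene, GO term), and are
collapsed to one record per symbol: GO terms unioned, description and
Entrez link taken from the first row (conflicts produce a warning). The
merge onto expression uses the gene symbol as a case-sensitive exact key:
predictable joins were preferred over a fuzzy/case-folding fallback that
could silently pair the wrong records. Annotation rows without expression
data are dropped with a logged count — the browser's universe is the
expression matrix.

## The lookup table

All statistics are precomputed once per dataset and persisted
(`stats_table.csv` plus a JSON sidecar carrying the pseudocount, group
order and MD5 hashes of the inputs; unchanged inputs reload instead of
recomputing). Per gene the table holds:

* **Group summaries.** Mean and SEM (`s/sqrt(n)`, sample standard
  deviation with the `n − 1` denominator) per group.
* **Experiment-wide one-way ANOVA** across all groups on the expression
  values as supplied, with no internal log transform. ANOVA on the raw
  scale is the conceptually simplest default and mirrors common microarray
  practice; users whose designs need count-aware models (negative-binomial
  GLMs, batch correction) should run those upstream and feed in the
  results — such models are deliberately out of scope here.
* **Pairwise contrasts.** For each of the `S(S−1)/2` group pairs, a Welch
  t test on the replicates. Welch (unequal variances,
  Welch–Satterthwaite df) was chosen over the pooled test as the robust
  default for small replicate groups; the two-group ANOVA F still equals
  the *pooled* t², and the test suite verifies that identity to ten
  significant digits.
* **q-values.** "FDR-adjusted p-value" here always means the
  Benjamini–Hochberg step-up, applied per family: the ANOVA p-values over
  all genes form one family, and each pairwise contrast forms its own
  family across genes. BH was chosen for being standard and
  assumption-light; no attempt is made to reproduce any particular
  historical implementation's choice, which is why numerical parity with
  other browsers' q-values is not claimed.

**Fold changes** are `log2((mean_a + ε)/(mean_b + ε))` with pseudocount
ε applied to both numerator and denominator. The default ε = 1 expression
unit keeps zero-expression genes (present in real data, e.g. the demo
table's all-zero rows) finite; ε is configurable and ε = 0 is legal for
strictly positive data.

**Degenerate genes.** Zero within-group variance is resolved explicitly
rather than left to floating point: all values identical gives F = 0,
p = 1; zero within-group variance with separated means gives p = 0 and a
`degenerate` flag. Flagged genes are excluded from the q-value filter
(with a message) because their q of exactly 0 reflects a variance
degeneracy, not evidence.

## Filters

Six criteria compose into one query. The three text criteria (symbol,
description, GO term) use case-insensitive *substring* matching —
browser-style search, not regular expressions — and are OR-combined with
one another: they act as a single "search box" facet. The numeric criteria
are AND-combined: expression range, fold change against a reference group,
and maximum ANOVA q.

Two semantics were genuinely open and are fixed as follows:

* *Expression range* applies to the **maximum group mean** of a gene: a
  gene passes `[lo, hi]` if its most expressed group lies in the range.
  This matches the browsing intent "is this gene expressed at this level
  anywhere?", and makes `[0, 0]` select exactly the all-zero genes.
* *Fold change* is two-sided: a gene passes when some non-reference group
  is at least `min_fold` above **or** below the reference, so a single
  query captures both up- and down-regulation.

Query results are ordered by ANOVA q ascending with alphabetical
tie-break. That ordering is also what "the first fifty transcripts" of the
heatmap means.

## Figures

Every builder returns the rendered plot together with the exact long-format
table it plotted. Tests assert on the tables; images are smoke-tested for
valid PNG output only.

* **Dot plots** (the default view): one panel per gene, group means with
  ±SEM bars, all panels on one shared y range so levels are comparable
  across panels. Capped at 25 panels — beyond that, filter first.
* **Volcano plots**: x is the stored contrast log2FC (no recomputation —
  the x axis is bit-identical to the lookup table), y is −log10 of the
  contrast q. q = 0 points (degenerate genes) are drawn at 110 % of the
  largest finite height so they stay visible without an infinite axis.
* **Difference plots**: per gene and group, the log2 difference from a
  reference gene's profile, coloured on a symmetric blue–yellow–red
  diverging scale over the observed range. Panels sort by the similarity
  score S(g) = mean |log2 difference| across groups — the simplest score
  that is zero exactly for a gene proportional to the reference (at ε = 0).
* **Heatmaps**: group means, transcripts × samples, black (low) to yellow
  (high). Pipeline order matters and is fixed: truncate to the first
  `max_rows` (default 50) genes of the incoming order, then optional
  `log2(x + ε)`, then optional row/column z-scoring (sd = 0 rows map to
  all-zero, not NaN), then optional hierarchical clustering with Euclidean
  distance and complete linkage (both configurable choices a practitioner
  may override upstream by reordering input).
* **PCA**: computed on `log2(mean + ε)` of the genes × groups matrix,
  column-centered, unscaled, via SVD. Points are transcripts; the loading
  bars show which sample groups drive the variation. Log transform before
  PCA keeps the decomposition from being dominated by a handful of
  extremely expressed genes (expression spans orders of magnitude).
  Component signs are fixed deterministically (largest-magnitude loading
  positive) so plots and tables are reproducible run to run.

## The synthetic-data generator

The generator produces files in exactly the dialects the readers ingest, so
simulated data exercise the same code path as user data. Per gene a
baseline `b ~ Normal(μ0, τ)` on the log2 scale; a fraction π of genes is
differentially expressed, receiving a `+δ` log2 shift in one randomly
chosen group (one affected group is the simplest structure identifiable by
a one-way ANOVA); replicates are `2^(b + shift + Normal(0, σ))`, or
negative binomial with matching mean and dispersion φ for count-like data.
Each gene carries 1–6 GO terms from a small synthetic vocabulary, and every
DE gene additionally carries a designated "planted pathway" term, so the GO
filter has a ground-truth target.

Defaults, chosen once as representative of replicated tissue RNA-seq:
500 genes, 4 groups, 3 replicates, π = 0.1, δ = 2 (a 4-fold shift),
μ0 = 6 and τ = 2 on the log2 scale, σ = 0.25 (typical replicate-level
variability of FPKM in tissue panels), lognormal noise. What the generator
deliberately does **not** emulate: library-size effects, batch structure,
gene–gene correlation, and mean–variance coupling beyond the NB option.
Passing recovery tests therefore demonstrates the statistical machinery is
correct under its own assumptions, not that ANOVA on raw expression is
optimal for any particular real design.

Recovery is quantified by `recovery_report()`: power (fraction of truly DE
genes with ANOVA q ≤ threshold) and realized FDR (fraction of calls that
are null). Under the defaults the test suite checks type-I error ≈ 0.05
under the global null (2000 genes), realized FDR ≤ 0.10 at q ≤ 0.05 with
π = 0.1 and δ = 2, power monotone in δ and replicate count, and mean log2FC
estimation bias below 0.05 at σ = 0.25 with 5 replicates (measured at
ε = 0, since the pseudocount is a deliberate shrinkage toward zero for
low-expression genes). Those problem sizes — 2000 genes for the error-rate
checks, 400–500 for the monotonicity and bias grids — keep the whole suite
comfortably under a minute while leaving binomial standard errors small
relative to the tolerances.

## Numerical choices and limitations

* Persisted tables are written at full double precision (`%.17g`;
  `Inf`/`NaN` spelled out) and reloaded with a correctly rounded parser, so
  save/load is exact and repeated builds are byte-identical.
* The parametric ANOVA p is validated against an exhaustive label
  permutation oracle on small two-group data; with ≤ 4 replicates per
  group the permutation null is coarse (70 distinct relabelings), so
  agreement is asserted within 0.15 rather than something tighter the
  discreteness cannot support.
* Case-sensitive symbol joins mean annotation files must use the same
  symbol casing as the expression table.
* The interactive browser layer (hover, zoom, live sessions) is out of
  scope; the figure-bundle table contract is the scriptable replacement
  for on-plot data export.
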