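---
title: "ctcflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctcflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ctcflow` analyses full-length single-cell RNA-seq profiles of circulating
tumor cells (CTCs) sampled at several vascular sites along the blood-flow
route — hepatic vein (HV), peripheral artery (PA), peripheral vein (PV) and
portal vein (PoV). It covers quality control, a pairwise-correlation
statistic of cell-to-cell heterogeneity, cell-cycle scoring and
cycling/noncycling classification, a staged differential-expression marker
cascade with gene-set over-representation, expression-based copy-number
inference against reference white blood cells (WBCs), a TF-to-target
correlation screen, and the hierarchical-clustering convention the other
stages share. Because the patient data this class of study rests on are
restricted-access, the package ships a synthetic-cohort generator with full
ground truth; every downstream stage is validated by recovering what the
generator planted.

# Quality control

Cells are kept when they have at least 3000 detected genes (FPKM > 0) and
strictly more than one million uniquely mapped reads. The boundary
semantics are literal and deliberately pinned by tests: 2999 genes fails,
exactly 1e6 reads fails, 3000 genes with 1,000,001 reads passes. Detected
genes are recomputed from the matrix whenever it is supplied — the matrix,
not the metadata, is the source of truth, and discrepancies are logged.
"1 M" is read as 1e6 reads. The expressed-gene filter keeps a gene only
when its FPKM exceeds 1 in strictly more than 10% of the analysed cells;
both inequalities are strict.

# Heterogeneity

For each site, the statistic is the Pearson correlation of
`log2(FPKM + 1)` between every unordered pair of CTCs, computed over the
2000 genes with the highest `log2(FPKM + 1)` variance across the analysed
population; the mean pairwise correlation summarises the site, and a lower
mean means a more heterogeneous site. Choices worth noting:

* Gene selection is computed on the pooled analysed cells even when the
  report is per patient; a per-patient selection is available by passing a
  cell subset.
* Variance ties at the cutoff are broken by ascending gene id so the
  selection is reproducible.
* Pairing is within patient by default: correlations between cells of
  different patients mostly measure patient effects, not within-site
  dispersion. Pooled cross-patient pairing is available as an option.
* Site distributions are compared with a two-sided Wilcoxon rank-sum test
  by default, with Welch's *t* as an option (and `test = "both"` to report
  both). The rank-sum default reflects that the correlation distributions
  are bounded and skewed.
* The pairwise correlations of one site share cells and are therefore not
  independent observations; the tests treat them as if they were, which is
  the field's convention for this statistic. Interpret the p-values
  accordingly.
* A pair in which one cell is constant over the selected genes has no
  defined correlation; such pairs are dropped and counted, never imputed.

# Cell-cycle scoring

Relative expression of gene *i* in cell *j* is
`E[i, j] = log2(FPKM[i, j] + 1) − mean_j log2(FPKM[i, ] + 1)`, i.e. each
gene is centred across the cells passed in, so every row of the result
averages to zero. A cell's G1/S score is the mean of `E` over the 42-gene
replication signature, and its G2/M score the mean over the 54-gene mitosis
signature (both shipped as a GMT under `inst/extdata` and user-overridable).
The centring population is exactly the cell set given to `cycle_scores()` —
typically all CTCs pooled; centre within a site by subsetting first.

Two classifiers are provided because the dendrogram-cut convention behind
"unsupervised hierarchical clustering of cycling genes" is not unique:

* `hclust2` — Ward linkage on Euclidean distance in the 2-D (G1/S, G2/M)
  score space, cut at two clusters; the cluster with the larger mean of
  `max(g1s, g2m)` is called cycling. Clustering the 2-D score space rather
  than the full 96-gene space keeps the rule auditable.
* `threshold` — cycling iff `max(g1s, g2m) >= 1` log2 unit, a transparent
  alternative useful for sensitivity analyses.

Both are design choices, documented as such, not reconstructions of any
particular study's dendrogram.

# Marker cascade

Differential expression between two cell groups proceeds in stages, each
strictly nested in the previous one (`final ⊆ potential ⊆ initial ⊆
tested`, asserted in code):

1. *CPM prefilter* — genes with CPM < 1 in more than two samples are
   removed. The "more than two" count is kept literal but exposed as a
   parameter: it is a reasonable rule for a dozen bulk samples and a harsh
   one for a hundred single cells.
2. *initial* — two-sided Wilcoxon rank-sum on `log2(x + 1)` per gene,
   |log2 fold change| > 1 (difference of group means of `log2(x + 1)`,
   pseudocount 1 — not a mean of per-cell ratios), p < 0.05 and BH q < 0.05
   over the tested genes.
3. *potential* — the group-mean fold change must exceed 1 log2 unit toward
   the up-group and the gene must be expressed (FPKM > 1) in at least 90%
   of the up-group cells.
4. *final* — a confirmatory rank-sum p < 0.05. With the rank-sum test as
   the core test this re-checks the stage-2 p-value; the stage exists so
   that a different stage-2 test (e.g. a negative-binomial count test via
   the adapter-style `exact_limit`/threshold parameters) still funnels
   through a nonparametric confirmation.

The rank-sum test is the single core test; a negative-binomial count model
would need count data, while this pipeline consumes FPKM-like continuous
values. Enrichment of a marker list against gene sets is an upper-tail
hypergeometric overlap test with BH adjustment across sets.

The rank-sum implementation enumerates all group labelings exactly up to a
combined sample size of 12 (exact under ties) and otherwise uses the normal
approximation with midrank tie correction and continuity correction; the
switchover is configurable.

# Expression-based CNV

Profiles are smoothed relative-expression tracks against reference cells:
genes with mean FPKM across all cells below 1 are removed
(`mean_cutoff = 1`, applied to raw mean FPKM, not its log); per-gene signal
is `log2(x + 1)` minus the reference-cell mean; a centred 201-gene moving
average runs along genome order within each chromosome, truncating at
chromosome edges (no cross-chromosome smoothing, no padding); each cell is
median-recentred to guard against library-size artifacts; finally a
sigmoidal denoiser multiplies each value by the logistic weight
`w = 1 / (1 + exp(−s (|v|/σ_ref − m)))` with midpoint `m = 2` reference
SDs and steepness `s = 4`. The midpoint follows the common
"sd_amplifier = 2" convention; the steepness has no canonical value and is
exposed as a parameter; the exact functional form of "attenuate values
near the reference mean" is a declared choice of this package. The weight
is monotone in `|v|`, so large signals pass essentially unchanged while
reference-level noise is crushed (tested at < 1% pass-through below half a
reference SD and > 99% above four).

A real limitation inherited from all expression CNV: any transcriptional
program that separates query cells from the reference (for example a
site-specific expression program) reads as a copy-number change. The CNV
tests therefore disable the generator's site programs to isolate the
planted segment; on real data, CNV calls inside strong program regions
deserve scepticism.

# TF screen

Candidate regulators are ranked by the Pearson correlation of their
`log2(x + 1)` expression with the target gene across cells, with two-sided
p-values from the *t* transform (exact permutation enumeration for ten or
fewer cells), BH adjustment, and a count of positively associated TFs
(r > 0, p < 0.05). The TF catalogue is always an input, never a default —
no embedded enhancer database; a user-supplied TF-to-target whitelist
serves that purpose when needed.

# Synthetic cohorts

`synthetic_spec()` defaults describe the cohort the package's tests
exercise: 45/12/40/16 CTCs in HV/PA/PV/PoV plus 8 WBC reference cells,
3000 genes, and lognormal base expression (gene means drawn once per
cohort from N(4, 1.5) in log2 units, cell-level noise SD 0.5). The
lognormal choice matches the right-skew of FPKM values; negative-binomial
counts are deliberately avoided because the pipeline consumes continuous
FPKM-like values. On top of the base layer:

* **Site programs** — each site has a 100-gene program whose per-cell
  activation is drawn from N(2, σ_site) log2 units. σ_site is the
  heterogeneity dial: the defaults 1.0/0.2/1.0/1.0 for HV/PA/PV/PoV make
  PA the markedly least dispersed site, the configuration the
  heterogeneity stage must recover.
* **Cycling cells** — per-site fractions default to 40%, 8.3%, 35% and
  56.3%; a cycling cell gets +2 log2 on its phase signature and half that
  on the other signature (`cycle_cross_leak = 0.5`). The leak reflects
  that replication and mitosis programs co-express in cycling cells; with
  a strictly single-set boost the two phases would sit on orthogonal axes
  of score space, a geometry no real cycling population shows.
* **DE genes, CNV segments, TF pair** — spiked fold changes in a chosen
  site; contiguous segments multiplying tumor-cell FPKM by a copy ratio
  (default one 2.0× block of 300 chr1 genes); and a TF/target pair built
  by residual orthogonalisation so the empirical log2-scale correlation
  over CTCs equals the requested value (default 0.86) exactly before any
  dropout.
* **Dropout** — independent Bernoulli zeroing of matrix entries,
  expression-independent, default rate 0. The model is off by default
  because expression-independent dropout plants zeros in highly expressed
  genes, creating log-scale outliers that no full-length protocol
  produces — real dropout concentrates in weakly expressed genes. Tests
  that probe dropout behaviour set the rate explicitly; treat nonzero
  rates as a stress knob, not as a calibrated noise model.
* **Seeding** — one mandatory seed drives a hierarchical stream with one
  substream per generative component, so enabling a component never
  perturbs the draws of another, and identical specs regenerate cohorts
  byte for byte.

Gene roles (cycle signatures, site programs, DE genes, TF pair) occupy
disjoint index blocks placed after the CNV span, so planted truths never
overlap; a genome too small for the requested layout is refused.

What the generator does **not** emulate: gene-length and GC effects,
expression-dependent dropout, doublets, patient-level batch structure
beyond a patient id, and correlated gene modules other than the planted
programs. Passing recovery tests therefore demonstrates that the
implementations compute what they claim on data with known structure — not
that the biological conclusions of any particular cohort would reproduce.

# Problem sizes

The test suite and the acceptance script run cohorts of 1500–3000 genes
and 12–121 cells: 100 cohorts for the heterogeneity ordering and the
43-TF screen, 20 for cycling recovery, 5 for the marker cascade, and
single cohorts for CNV and determinism checks. These sizes give
Monte-Carlo stability (binomial SE below 3 percentage points on the
success rates) while keeping a full run in well under a minute per stage.

# Known limitations

* Pairwise correlations within a site share cells; the site-comparison
  p-values ignore this dependence (field convention, noted above).
* The CNV stage cannot distinguish broad transcriptional programs from
  copy-number changes.
* The cascade's confirmation stage is redundant when the core test is
  already the rank-sum test.
* The generator's dropout model is a stress knob, not a realistic noise
  model.
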