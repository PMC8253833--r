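# ctcflow

Analysis toolkit for full-length single-cell RNA-seq of circulating tumor
cells (CTCs) sampled at multiple vascular sites along the blood-flow route —
hepatic vein (HV), peripheral artery (PA), peripheral vein (PV) and portal
vein (PoV). Hematogenous dissemination exposes CTCs to shear stress, oxygen
deprivation and immune surveillance, and their transcriptomes shift from
site to site; `ctcflow` implements the computational procedures such studies
rely on, end to end, with a synthetic-cohort generator that makes every
stage testable without access to restricted patient data.

## What it computes

* **QC** — cells kept with ≥ 3000 detected genes (FPKM > 0) and > 1e6
  uniquely mapped reads; expressed-gene filter (FPKM > 1 in > 10% of
  cells). Boundary semantics are literal and tested.
* **Heterogeneity** — for each site, Pearson *r* of log2(FPKM + 1) over the
  top-2000-variance genes for every unordered CTC pair; mean pairwise *r*
  per site (lower = more heterogeneous), sites compared by two-sided
  Wilcoxon rank-sum (Welch *t* optional).
* **Cell cycle** — relative expression
  *E*<sub>*i*,*j*</sub> = log2(FPKM<sub>*i*,*j*</sub> + 1) −
  mean<sub>*j*</sub> log2(FPKM<sub>*i*,·</sub> + 1), averaged over a
  42-gene G1/S and a 54-gene G2/M signature; cycling cells classified by a
  2-cluster Ward cut in score space or a plain threshold.
* **Marker cascade** — CPM prefilter; per-gene rank-sum test with
  |log2FC| > 1, p < 0.05, BH q < 0.05 (*initial*); fold change > 1 toward
  the up-group and expressed in ≥ 90% of up-group cells (*potential*);
  confirmatory p < 0.05 (*final*). Hypergeometric gene-set enrichment of
  the result.
* **Expression CNV** — reference-centred log2 signal, 201-gene moving
  average along genome order, per-cell median recentring, logistic
  denoising with midpoint 2 reference SDs.
* **TF screen** — Pearson correlation of each candidate TF with a target
  gene (the MAX→CCL5-style screen), *t*-based p, BH q, ranking.
* **Synthetic cohorts** — lognormal expression with site programs of
  controllable cell-to-cell dispersion, cycling subpopulations, spiked DE
  genes, CNV segments, a TF/target pair at an exact requested correlation,
  and full ground truth for recovery testing.

The statistical primitives (exact-enumeration Wilcoxon rank-sum, BH
step-up, upper-tail hypergeometric) are self-contained and verified against
brute-force oracles in the test suite.

## Worked example

```r
library(ctcflow)

co <- generate_cohort(synthetic_spec(seed = 7))
co$matrix
#> Expression matrix [FPKM]: 3000 genes x 121 cells

filter_cells(co$matrix, co$cells)
#> QC: 121/121 cells pass (min genes 3000, reads floor 1e+06)

ctc   <- co$cells$cell_id[co$cells$cell_class == "CTC"]
genes <- select_variable_genes(co$matrix, 2000, cell_subset = ctc)
site_heterogeneity(co$matrix, co$cells, genes)
#> Heterogeneity over 2000 genes (within_patient pairing)
#>   HV   mean r = 0.8419 (990 pairs)
#>   PA   mean r = 0.8778 (66 pairs)
#>   PV   mean r = 0.8549 (780 pairs)
#>   PoV  mean r = 0.8420 (120 pairs)
#>   HV_vs_PA: p = 2.76e-30 (wilcoxon_rank_sum)
#>   ...
```

PA has the highest mean pairwise correlation — the least heterogeneous
site, exactly the structure the generator planted (program dispersion 0.2
in PA vs 1.0 elsewhere), and the rank-sum comparison calls the difference
decisively.

```r
sc <- classify_cycling(cycle_scores(co$matrix[, ctc],
                                    co$sets$G1S, co$sets$G2M,
                                    cells = co$cells), "hclust2")
cycling_proportions(sc)
#>   site  n n_cycling percent
#> 1   HV 45        21    46.7
#> 2   PA 12         0     0.0
#> 3   PV 40        12    30.0
#> 4  PoV 16         8    50.0

screen_tfs(co$matrix, c(co$truth$tf_id, co$truth$null_tf_ids),
           co$truth$target_id, cells = ctc)
#> TF screen vs g00998 over 113 cells: 43 TFs, 1 positive (r > 0, p < 0.05)
#>       tf         r            p            q rank
#> 1 g00997 0.8603538 2.844119e-34 1.222971e-32    1
#> ...
```

The recovered per-site cycling percentages track the planted fractions
(40/8.3/35/56.3), and the one TF coupled to the target at *r* = 0.86 tops
the 43-TF screen at *r* = 0.860.

The whole pipeline also runs from one config:

```r
run_pipeline(list(seed = 7), outdir = "run1")   # qc/het/cycle/markers/cnv/tf/cluster
```

which writes stage CSV/JSON outputs, a resolved `config.json` and a
`manifest.csv` of md5 checksums; identical config + seed reproduce the
manifest byte for byte.

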