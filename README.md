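# ssmtx

Differential expression and contamination QC for sorted lymph node
macrophage transcriptomes.

Sub-capsular sinus macrophages (SSM, CD169+ CD11c−) and medullary sinus
macrophages (MSM, CD169+ CD11c+) are fragile, rare populations: profiling
them means sorting small numbers of cells, pooling mice, and worrying that
membrane blebs shed during dissociation have dragged B- and T-cell
transcriptomes into the sorted gates. ssmtx implements the computational
workflow for exactly this setting, for bioinformaticians analysing sorted
myeloid bulk RNA-seq:

* **Differential expression** on a pooled factorial design (4 pools ×
  tumor-draining status × CD11c phenotype = 16 samples): gene filtering
  (total count ≥ 10, detected in ≥ 2 samples), median-of-ratios size
  factors, and per-gene negative binomial GLMs
  `log μ = log c_s + b0 + b1·Pool + b2·TD + b3·Phenotype`
  tested by likelihood ratio against the model without the factor of
  interest (comparison **C1**: phenotype, adjusting for pool and TD;
  **C2**: TD, adjusting for pool and phenotype), χ²₁ reference, Holm
  adjustment, and DEG calls at `p_holm < 0.01` & `base_mean > 100`.
  Fold changes are signed so that positive = up in SSM (C1) or up in
  tumor-draining nodes (C2).
* **Cross-platform harmonization** against legacy microarray data: probe →
  gene averaging, log2(CPM+1) for counts, platform gene intersection,
  per-sample z-scoring, platform-wise means and a Pearson comparability
  coefficient.
* **Contamination QC**: B-cell / T-cell / macrophage / housekeeping marker
  signatures (sums of standardized expression), housekeeping-referenced
  ratios, and exact Mann-Whitney comparisons between datasets.
* **A synthetic-data generator** emulating the full design — NB counts with
  gene-specific means and dispersion, phenotype/TD effects, pool
  perturbations, library sizes, and lymphocyte contamination as a convex
  mixture fraction `f` per sample — plus a microarray-like twin dataset,
  with ground truth attached. All calibration claims in the test suite are
  checked against this generator.

## Worked example

```r
library(ssmtx)

cfg    <- sim_config(n_genes = 500, seed = 42)   # 16-sample study emulation
sim    <- generate_counts(cfg)
counts <- filter_genes(sim$counts)
fit    <- run_comparison(counts, comparison = "C1")
print(fit, n = 4)
#> NB GLM likelihood-ratio test, comparison C1 (tested: phenotype+)
#> 500 genes x 16 samples; 0 gene(s) failed to converge
#>    gene_id base_mean log2_fc dispersion lrt_stat     p_raw    p_holm converged
#>  gene00098     246.9   -2.13     0.0119    463.2 9.46e-103 4.73e-100      TRUE
#>  gene00039     415.9    2.21     0.0267    286.0  3.73e-64  1.86e-61      TRUE
#>  gene00069    1980.0    2.04     0.0303    237.8  1.17e-53  5.81e-51      TRUE
#>  gene00093     413.1    2.17     0.0331    229.1  9.47e-52  4.71e-49      TRUE
#> ... 496 more genes
summary(fit)
#> Comparison C1: 500 genes tested (500 converged)
#> DEGs at p_holm < 0.01 and base_mean > 100: 29 up, 16 down
#> Dispersion quartiles: 0.0201 / 0.0447 / 0.0755
#> Size factors in [0.62, 1.9]
```

The top genes are the generator's spiked phenotype effects (true |log2FC|
= 2), recovered with the right magnitude and sign; `gene00098` is higher in
MSM, hence negative under the SSM-positive convention. `summary()` counts
DEG calls at the default thresholds; `coef()`, `plot()` (MA plot) and
`select_deg()` expose the rest of the fit.

Contamination QC against the simulated legacy microarray twin (8 samples at
mixture fraction 0.25 vs 0.02 in the RNA-seq arm):

```r
probes <- generate_microarray(sim$truth, cfg)
h      <- harmonize_platforms(counts, probes)
#> [harmonize] 500 shared genes, cross-platform Pearson r = 0.9605
qc     <- contamination_report(h$rnaseq, h$microarray)
qc$comparison
#>       panel n_a n_b median_a median_b   U         p method
#>       bcell  16   8   0.7182    1.032   0 2.719e-06  exact
#>       tcell  16   8   0.8810    1.253   0 2.719e-06  exact
#>  macrophage  16   8   1.1250    1.088 119 2.611e-04  exact
```

The B/T ratios are markedly higher in the contaminated dataset (dataset
"b"), while the macrophage ratio moves the other way — lymphocyte material
dilutes macrophage markers. The same stages run from the shell over TSV
files via `run_pipeline()` / `inst/scripts/run_pipeline.R`, which writes
per-stage TSV/JSON outputs, a record-count manifest and the resolved YAML
config, byte-reproducibly for a fixed seed.

See the methods vignette (`vignettes/ssmtx-methods.Rmd`) for the model
details, the generator's assumptions, and an honest account of the
calibration limits of per-gene dispersion estimation at n = 16.

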