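---
title: "Models and methods behind ssmtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssmtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmtx)
```

# The analysis problem

ssmtx analyses bulk RNA-seq of two sorted lymph node macrophage
populations — CD169+ CD11c− sub-capsular sinus macrophages (SSM) and CD169+
CD11c+ medullary sinus macrophages (MSM) — profiled in a pooled factorial
design: 4 biological-replicate pools (lymph nodes of 2 mice each), and for
each pool the four sorted fractions CD11c+/− × tumor-draining (TD = 1) /
non-draining (TD = 0) lymph node, i.e. 16 samples. Two questions drive the
statistics:

1. **Differential expression.** Which genes differ consistently between the
   CD11c phenotypes (comparison C1), and which respond to tumor drainage
   (comparison C2), adjusting in both cases for the pool blocking factor
   and the other design factor?
2. **Contamination QC.** Sorted macrophage preparations are notoriously
   contaminated by lymphocytes: fragile macrophages shed membrane blebs
   during dissociation that stick to B and T cells, so "macrophage" gates
   can contain lymphocyte transcriptomes. How much lymphocyte signal does a
   dataset carry, and is a newly sorted dataset cleaner than a legacy one
   measured on a different platform (microarray)?

# Differential expression model

Counts for each gene are modelled as negative binomial (NB) with mean
$\mu_{gs}$ and dispersion $\alpha_g$, $\mathrm{Var} = \mu + \alpha\mu^2$,
with a log link:

$$\log \mu_{gs} = \log c_s + \beta_0 + \beta_{\text{pool}(s)} +
\beta_{\text{td}}\,\mathrm{TD}_s + \beta_{\text{ph}}\,\mathrm{CD11c}^+_s$$

where $c_s$ are median-of-ratios size factors (rescaled to geometric mean
1). Both comparisons share this full model; the reduced model drops the
factor under test (phenotype for C1, TD for C2). Factors use treatment
coding with pool 1, TD = 0 and phenotype "−" (SSM) as references. Each gene
is tested by the likelihood-ratio statistic $2(\ell_{\text{full}} -
\ell_{\text{reduced}})$ referred to $\chi^2_1$; p-values are Holm-adjusted
per comparison (each comparison publishes its own gene table, so the family
is the comparison). Reported fold changes follow the SSM-positive
convention: under C1, $\log_2\mathrm{FC} > 0$ means higher in CD11c− (SSM)
samples; under C2, higher in tumor-draining nodes. A gene is called
differentially expressed when `p_holm < 0.01` **and** `base_mean > 100`
(both strict), `base_mean` being the average of size-factor-normalized
counts over all samples.

## Dispersion estimation and its consequences

$\alpha_g$ is estimated per gene, with no information sharing across genes:
the fit alternates IRLS for $\beta$ with a one-dimensional search over
$\log\alpha$, maximizing the Cox-Reid (CR) adjusted profile likelihood
$\ell(\alpha) - \tfrac12\log\det(X^\top W X)$, started from a
method-of-moments value and floored at $10^{-8}$. The CR adjustment matters
here: the full design spends 6 of 16 degrees of freedom on the mean, and
unadjusted maximum likelihood underestimates $\alpha$ enough to roughly
double the nominal type-I error of the LRT.

Two honest caveats follow from the per-gene strategy, both visible in the
package's own calibration checks (`scripts/acceptance.R` recomputes them):

* **Mild global anticonservativeness.** With $n = 16$ the per-gene
  $\hat\alpha$ is noisy (its log-scale standard deviation is of order
  0.5–1), and plugging a noisy dispersion into a $\chi^2$ LRT inflates the
  5% rejection rate under the null to roughly 6–8%. With the true
  dispersion supplied the same machinery is exactly calibrated, so this is
  purely the price of estimating $\alpha$ from 16 observations.
* **Far-tail collapse events.** Occasionally $\hat\alpha$ collapses toward
  the floor for a gene whose contrast is, by chance, large; the LRT then
  compares an overdispersed contrast against a near-Poisson likelihood and
  produces a spuriously extreme p-value. This inflates the far tail (the
  region that matters for Holm at 0.01 over thousands of genes) much more
  than the 5% level, so familywise error control under permuted labels
  falls short of its nominal guarantee.

Both problems are exactly what dispersion moderation (trend + empirical
Bayes shrinkage, as in DESeq2/edgeR, or the quasi-likelihood F-test) was
invented to fix. ssmtx deliberately implements the plain per-gene model —
the transparent, literally-stated form of the analysis — and documents the
cost rather than silently moderating. Consequently, gene lists on real data
will not match DESeq2 exactly, and borderline Holm-significant genes with
small fitted dispersions deserve skepticism.

## Numerical choices

IRLS converges on a relative coefficient change of $10^{-8}$ (max 100
iterations); linear predictors are bounded at ±30 on the natural-log scale
so separated or all-zero genes stay finite; the dispersion search runs over
$\alpha \in [10^{-8}, 10^3]$ with tolerance $10^{-4}$ on $\log\alpha$ and
the reduced model reuses the full-model dispersion (the test compares mean
structure only); the LRT statistic is clamped at 0; non-converged genes are
reported but excluded from testing and from the Holm family. Holm ties need
no tie-break (tied raw p-values receive identical adjusted values); result
tables order by `(p_holm, |log2_fc| decreasing, gene_id)` for
reproducibility.

# Cross-platform harmonization

The comparison of an RNA-seq dataset against a legacy microarray dataset
proceeds exactly in this order:

1. **Probe aggregation** — microarrays carry several probes per gene;
   probe-level log2 intensities are averaged per gene (arithmetic mean on
   the log2 scale, the scale arrays are reported on).
2. **Count transform** — RNA-seq counts become $\log_2(\mathrm{CPM} + 1)$.
   The pre-log normalization is a genuine choice (`log2cpm1` default,
   `log2count1` available): CPM removes depth differences before the
   per-sample z-score, and the z-score then makes the result insensitive to
   any remaining multiplicative constant.
3. **Platform intersection** — genes detected on only one platform are
   dropped. "Detected" is operationalized as: at least one sample with a
   positive count (RNA-seq) or at least one non-missing intensity (array);
   dropped counts are logged so the choice is auditable.
4. **Per-sample standardization** — each sample column is z-scored
   (n − 1 denominator; with 16 samples the denominator choice is
   immaterial but is fixed for exactness). Intersection precedes
   standardization, matching the order in which the workflow is described;
   standardizing first would leave column moments depending on
   platform-specific genes.
5. **Platform means and comparability** — per-gene averages over each
   platform's samples, compared by Pearson correlation. On paired synthetic
   platforms with zero array noise the chain returns $r = 1$ to machine
   tolerance; $r$ degrades smoothly as probe noise grows.

# Lineage signatures and contamination ratios

Four marker panels (ImmPort-derived mouse symbols, matched verbatim) are
scored per sample as the **sum** of the panel genes' standardized values:
B cell (9 genes), T cell (11), macrophage (9), and a housekeeping reference
panel (8) whose low variability makes it the denominator. Because z-scores
can be negative, a raw ratio would be ill-defined; the default
`shift = "minzero"` subtracts the global minimum of the harmonized matrix
(the minimum over *both* datasets, so they share one scale) before summing,
guaranteeing positive signatures while preserving sample ordering within a
panel. Missing panel genes (a real possibility after platform intersection)
are skipped with a warning and reported via `n_markers_found`. Per-sample
ratios — not platform aggregates — feed a two-sided Mann-Whitney test per
panel, since a rank test needs per-sample observations.

The Mann-Whitney implementation enumerates the exact permutation null of
the U statistic (counting recurrence; two-sided p = twice the smaller tail,
capped at 1) whenever the data are tie-free and $\min(n_1, n_2) \le 8$, and
otherwise uses the tie-corrected, continuity-corrected normal
approximation.

# What the synthetic generator emulates

`generate_counts()` draws the 16-sample design from a two-compartment
mixture: for gene $g$ and sample $s$,

$$\mu_{gs} = L_s \, \pi_{g,\mathrm{pool}(s)} \left[(1 - f_s)\, m_g\,
2^{\text{effects}} + f_s\, l_g\right],$$

then $y_{gs} \sim \mathrm{NB}(\mu_{gs}, \alpha)$. Here $m_g$ is the
macrophage-compartment mean (log2-uniform over `baseline_log2_mean_range`,
default 1–10, i.e. 2–1024 expected reads), $l_g$ the lymphocyte compartment
(≈512 for B/T markers, 0 for macrophage markers, equal to $m_g$ for
housekeeping and background genes), $f_s$ the per-sample bleb-contamination
fraction, $\pi$ a small shared-within-pool log-normal perturbation
(`pool_sd_log2` = 0.1, giving the pool adjustment something real to
absorb), and $L_s$ a log-uniform library-size factor (0.5–2, folded into
$\mu$ so size-factor recovery is testable). Defaults represent the study
conditions: dispersion 0.05 (typical for pooled biological replicates),
contamination 0.02 for the well-sorted RNA-seq arm, 100 phenotype-affected
genes at ±2 log2 units and 30 TD-affected genes at ±1 among the background
genes, disjoint from the marker panels.

The microarray twin (`generate_microarray()`) represents the legacy
comparison dataset: by default 8 of its own samples at contamination 0.25.
Two design points matter and were chosen for self-consistency:

* Array samples are **NB realizations** of their expected mixture
  expression, not noiseless expectations — biological replicates exist on
  both platforms. Without this, any per-gene platform bias dominates the
  (tiny) within-array variance and the equal-contamination null of the
  panel comparison rejects wildly; with it, the null rejection rate sits at
  its nominal level (the test suite checks 0.05 ± 0.02 over 1000
  replicates).
* Probe affinity offsets (sd 0.3) are **centered within each gene**: the
  gene-level abundance is *defined* as the average over its probes, so
  probe aggregation recovers gene values exactly when measurement noise
  (`noise_sd_array`, default 0.25 log2 units) is zero.

All draws consume a single seeded RNG in documented order, so outputs are
bit-reproducible, and the caller's RNG state is restored.

What the generator does **not** emulate: read-level artifacts (no FASTQ, no
mapping bias), platform-specific probe chemistry beyond offsets + Gaussian
noise, correlated genes (all genes are independent given the design),
GC/length effects, or the large silent fraction of an annotated
transcriptome — background genes are drawn at detectable levels, so the
count filter (total ≥ 10, detected in ≥ 2 samples) rarely removes synthetic
genes even though it removes most of a real annotation. Passing tests
therefore demonstrate correctness of the machinery and calibration under
the stated model, not robustness to real-data pathologies.

One model-inherent caveat for the contamination QC: because macrophage
markers are absent from lymphocytes, a convex mixture necessarily *dilutes*
them by $(1 - f)$. Comparing f = 0.02 against f = 0.25 therefore shifts the
macrophage signature by $\log_2(0.75/0.98) \approx -0.39$, several
within-group standard deviations, and the macrophage panel comparison
detects contamination differences of this size essentially always — the
macrophage panel is only "stable" between datasets whose contamination
difference is small relative to biological noise. The housekeeping
reference, present equally in both compartments, is genuinely invariant.

# Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
desk scale, chosen as the smallest sizes that make the Monte-Carlo bounds
meaningful: 2,000-gene matrices for calibration and effect-recovery checks
(10 and 5 seeds respectively), 200-gene matrices × 100 (tests) or 50
(script) replicates for the permuted-label familywise-error check,
150-gene matrices × 100–1000 replicates for contamination power and null
calibration, and exhaustive enumeration up to group sizes 8 × 8 for the
exact Mann-Whitney oracle.

# Known limitations

* Per-gene dispersion + $\chi^2$ LRT is anticonservative at n = 16 (see
  above); treat borderline calls accordingly.
* The contamination module scores and tests signatures; it does not
  estimate $f$ by deconvolution.
* Gene identifiers are opaque case-sensitive strings; no alias resolution
  is attempted, so marker panels must match the annotation verbatim.
* No GO/pathway enrichment, quantile normalization, batch correction, or
  probe re-annotation.
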