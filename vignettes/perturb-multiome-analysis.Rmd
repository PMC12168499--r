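---
title: "Perturbation scoring, TF-sensitivity and variant enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation scoring, TF-sensitivity and variant enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

perturbscope analyses pooled CRISPR knock-out screens of transcription
factors (TFs) read out with paired single-cell RNA and ATAC profiling.
This vignette is the package's account of the statistics it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical decisions a maintainer would want written down.

## 1. Perturbation scores

**Problem.** Gene editing is incomplete (a guide's efficiency can be well
below 1) and cells are spread along a differentiation continuum, so "has
guide X" is a poor proxy for "is perturbed". We therefore quantify, per
cell and per modality, how far the cell's molecular profile departs from
comparable unperturbed cells *in the direction characteristic of its
target*.

**Procedure.**

1. *Normalization.* RNA counts are scaled to a fixed depth (default
   10,000) and transformed `log2(1 + x)`, so downstream effects are log2
   fold changes. ATAC counts get TF-IDF weighting (term frequency by cell,
   inverse document frequency by peak), the standard weighting for sparse
   accessibility data, then the same log transform.
2. *Embedding.* RNA: the 2,000 most variable features, centered, PCA to 30
   components. ATAC: truncated SVD of the TF-IDF matrix (LSI) with the
   first component dropped, because it tracks sequencing depth almost
   perfectly. These are the standard single-cell conventions; all four
   numbers (`dims = 30`, `n_features = 2000`, depth target, `k` below) are
   exposed as arguments.
3. *Signature.* For each cell, `signature = normalized profile − mean
   normalized profile of its k = 20 nearest control cells` (non-targeting
   plus safe-harbor guides) in the embedding, Euclidean distance. Control
   cells are scored against the other controls, excluding themselves.
   Nearest-neighbor controls share the cell's differentiation state, so
   the subtraction removes the differentiation program and leaves the
   perturbation response.
4. *Score.* Per target, a unit direction vector = the mean signature over
   all cells carrying that target's guides. A cell's raw score is the
   projection of its signature onto its own target's direction; every
   control cell is additionally scored against every target. z-scores are
   `(raw − mean_control)/sd_control` per target and modality, so control
   z-scores have mean 0 and SD 1 by construction. A threshold of `z > 2`
   is the conventional "clearly perturbed" cutoff used for group
   contrasts.

**Assumptions.** The perturbation response is approximately a fixed
direction in feature space per TF (first-order); controls at a similar
embedding position are a valid counterfactual; `k = 20` trades neighbor
noise (small k) against differentiation-stage mismatch (large k).

## 2. TF-sensitivity calls

Per feature `g`, TF `t` and modality, over the cells carrying `t`'s guides
plus all controls:

    y_g = α + β·z + γ·log10(total counts) + ε

with `y_g` the normalized value. Two deliberate deviations from the
textbook version, both forced by calibration:

* **Leave-one-feature-out covariate.** The projection score contains
  feature `g`'s own noise times `g`'s weight in the direction vector. If
  that same score is the regression covariate for `g`, the slope picks up
  a genuine nonzero component under the null (the shared noise term), and
  the null t-statistic is inflated by a factor that grows with
  cells/features — our null simulations fail both FDR control and p-value
  uniformity with the naive covariate. The fix is exact: for feature `g`
  the covariate is the projection with `g`'s own term removed,
  re-standardized on controls. The score *table* (used for thresholds,
  figures, efficiency correlations) keeps the full projection.
* **Instrumental-variable effect size.** `z` measures the achieved
  perturbation level with error, so the OLS slope is attenuated
  (regression dilution); in simulations with known effects the recovered
  effect was ~0.6–0.7 of truth, irrespective of sample size. The reported
  `log2FC = β_IV · (mean z of TF cells − mean z of controls)` instead
  uses the slope instrumented by the carries-TF-guide indicator, which is
  immune to dilution; algebraically the product equals the
  covariate-adjusted TF-vs-control mean difference on the log2 scale.
  The *test* stays the OLS Wald test on the continuous z: it is correctly
  calibrated under the null and more powerful than a two-group test when
  efficiency varies, because z separates edited from unedited cells
  within the TF group. Reporting an effect estimator different from the
  test statistic's slope is deliberate and documented, in the same spirit
  as shrunken effect estimates in differential-expression packages.

Benjamini–Hochberg correction is applied within each (TF, modality)
stratum; `q < α` (default 0.05) flags a feature sensitive. Zero-variance
features are kept with `p = 1`, effect 0. Degenerate designs error:
fewer than 50 cells, no TF cells, or a singular covariate matrix.

Expected recovery: with editing efficiency `e` and log1p count compression
`κ` (≈0.9–0.97 for moderately expressed features), the estimand is
`e·κ·δ` for a planted per-edited-cell effect `δ` — unedited cells carrying
the guide genuinely dilute the population effect. The acceptance suite
checks recovery within ±0.2 of a planted `δ = 1` at `e = 0.95`.

`summarize_sensitive()` reports, per modality, features sensitive to ≥ 1 TF
as `round(100·s/t, 1)` percent plus the fraction responding to exactly one
TF. `group_contrast()` implements the figure-style Wilcoxon contrast of
`z > 2` cells vs safe-harbor controls. `replicate_concordance()` is the
Spearman correlation of (z-scored) log2FC over features significant in
both replicates; z-scoring per table is monotone, so the correlation is
computed on the effect sizes directly.

## 3. Regulatory linkage

* **Pair enumeration**: all (ACR, gene) with |peak midpoint − TSS| ≤ 50 kb
  (2 Mb for the TAD analysis); distance signed by gene strand, upstream
  negative. Peak anchor = `floor((start + end)/2)`.
* **Pair correlation**: Spearman (average ranks for ties) between
  normalized accessibility and expression across *non-targeting* cells
  only — the perturbation-free baseline. Zero-variance members yield `NA`
  with a message, never an error.
* **CRISPRi overlap**: Fisher's exact two-sided test on {pair jointly
  TF-sensitive} × {pair in the validated link set}; sample odds ratio
  `ad/bc`, 95% CI by the log-normal approximation with a Haldane–Anscombe
  0.5 correction applied (to the CI, and to the point estimate only when
  a cell is zero, flagged `degenerate`).
* **TAD co-occupancy**: a pair is "in TAD" when peak midpoint and TSS fall
  strictly inside the *same* TAD interval (boundary-touching pairs do not
  count; TADs must be non-overlapping per chromosome). Per
  genomic-distance bin (default logarithmic, 10 kb–2 Mb), the sensitive
  pairs' odds are compared with 100 resamples of equally many
  non-sensitive pairs matched on the 10×10 decile grid of mean
  accessibility × mean expression (falling back to the whole bin when a
  grid cell is empty); the null mean ± SD is reported.
* **ChIP proximity**: ACRs are binned by signed midpoint distance to the
  nearest ChIP peak center within a window (default ±5 kb, 20 bins);
  the profile is the mean −log10(p) per bin, with p floored at 1e-300.

## 4. Variant enrichment

* **Credible-set overlap**: a 95% credible set overlaps a region set when
  ≥ 1 of its variants' positions falls in ≥ 1 region (0-based half-open
  containment). PIPs are deliberately not used for overlap.
* **Resampling nulls**: `matching = "length"` draws regions from a
  candidate pool matching each observed region's length within ±20%
  (nearest length as fallback); `matching = "random"` places same-length
  intervals uniformly on the genome. 100 draws give the null mean and SD;
  one draw reports SD as `NA`.
* **Heritability enrichment**: `(Σh² in category / Σh² total) /
  (n in category / n total)` on per-SNP heritability contributions.
  Complementary categories satisfy `p·E_in + (1−p)·E_out = 1` exactly.
  Full stratified LD-score regression is *not* implemented: it requires
  external LD reference panels; the ratio is computed on per-SNP
  contribution tables (known exactly in simulation, accepted as input for
  real data).
* **Constraint ECDFs**: per-category empirical CDFs on the pooled score
  grid with pairwise two-sample KS tests (ties handled by the asymptotic
  test); categories with < 2 records are excluded with a message.
* **Trait-relevance score**: a documented simplified stand-in for
  published deviation-style scores: per cell, the fraction of counts in
  the trait peak set minus the mean over 50 background peak sets matched
  on total-accessibility decile, divided by their SD.

## 5. The synthetic world

`simulate_dataset()` emulates the statistical structure of a
differentiation-coupled Perturb-multiome experiment on one synthetic
chromosome (default 20 Mb, 0-based half-open coordinates):

* design: 19 TFs × 3 guides + 6 controls (3 non-targeting, 3 safe-harbor),
  one guide per cell, uniform multinomial assignment;
* per-guide editing efficiencies uniform in a configurable range (default
  0.4–0.95, mirroring the wide spread seen in pooled genotyping without
  copying specific values); edited flags drawn per cell;
* a per-cell pseudotime in [0, 1]; 20% of genes/peaks follow smooth
  pseudotime programs (log2 slope ±1 for genes, logit slope ±2 for peaks);
* RNA: negative binomial (dispersion 0.5) with lognormal size factors
  (CV ≈ 0.3) around a mean depth of 10,000, gene means lognormal;
  ATAC: Poisson at depth 5,000 with per-peak open-probability on the
  logit scale; peaks fixed-width 500 bp, non-overlapping;
* planted effects: per TF, 25 sensitive genes drawn from the
  upper-half-expressed genes (TF targets are expressed genes; this also
  keeps log1p compression mild) with `δ = sign ×
  effect_size_log2fc × U(1−jitter, 1+jitter)` (jitter 0.5 — real TF
  effect magnitudes are heterogeneous; constant magnitudes would also
  make replicate rank-concordance a pure noise measurement); 50 sensitive
  peaks with logit shifts `δ·ln 2`; half the sensitive peaks are *linked*:
  placed within 50 kb of a same-TF sensitive gene's TSS inside a shared
  TAD, with matching effect sign, and co-regulated at baseline (both
  members share a pseudotime program), so linked pairs correlate in
  control cells as real enhancer–gene pairs do;
* `simulate_genotypes()`: TF cells genotyped with probability `coverage`,
  flags flipped with probability `call_error`, controls never called;
* `simulate_gwas()`: a SNP panel placed uniformly plus preferentially in
  peaks, with effect-size variance multiplied by `enrichment_factor`
  inside TF-sensitive peaks (so the expected partitioned enrichment
  equals the factor); credible sets of one causal SNP (PIP 0.6) plus
  LD companions within ±25 kb sharing 0.4 uniformly.

**What it does not emulate** — and hence what a green test does not
establish: doublets, ambient RNA, batch and donor effects, multiple
chromosomes, realistic LD structure, peak-calling artifacts, lineage
branching (pseudotime is a single axis), and guide mis-assignment. The
calibration results certify the statistics under the stated generative
model, not robustness to these nuisances.

## 6. Numerical decisions

* Truncated SVD above 500 cells/features uses deterministic subspace
  iteration (10 iterations, 8 oversampling columns, initialized from the
  data itself) with a Rayleigh–Ritz rotation; below that, exact `eigen` of
  the smaller Gram matrix. No RNG state is touched, so embeddings are
  bit-reproducible and independent of seed handling.
* All randomized operations (`simulate_*`, resampling nulls, TRS
  backgrounds, the pipeline stages) take explicit seeds; `run_all()`
  derives per-stage seeds from one global seed via a deterministic hash
  kept below 2^31, so stages can be re-run in isolation.
* BED-style interval inputs are validated line-by-line (start < end,
  numeric coordinates) with the offending line number in the error;
  sorting is stable for ties.
* Ties in Spearman correlations use average ranks; `wilcox.test`'s exact
  p is used automatically for small tie-free samples.
* The null-calibration acceptance check uses the pooled-p KS *statistic*
  (D < 0.05) rather than a KS p-value: with ~10^5 weakly dependent
  p-values, any fixed-significance test would reject for deviations of no
  practical consequence; D bounds the worst-case CDF deviation directly.
* Degenerate inputs are policy, not accidents: zero-variance features are
  retained with `p = 1`; empty TAD bins and tiny ECDF categories are
  skipped with messages; all-in/all-out odds tables are Haldane-corrected
  and flagged; an efficiency correlation over zero-variance guides is
  `NA`, not an error.

## 7. Known limitations

* The perturbation-score projection is a stand-in for the original
  supplementary definition (not public); it is validated against the
  behavior that definition must exhibit (control calibration, threshold
  semantics, efficiency correlation), not against its exact values.
* The linear model covariates are intercept + log-depth; cell-cycle or
  lineage covariates are not modeled, and lineage-restricted TF effects
  (a TF acting mostly outside the assayed lineage) will score low by
  design.
* Heritability enrichment assumes per-SNP contributions are supplied or
  simulated; it is not an LDSC replacement.
* The trait-relevance score is a simplified deviation score; it shares the
  spirit, not the implementation, of published methods.
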