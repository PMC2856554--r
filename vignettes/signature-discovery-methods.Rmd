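---
title: "Methods: cross-validated RFS signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-validated RFS signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the tunable parameters, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices made where the field's conventions leave the procedure open.

## The discovery procedure

The pipeline targets right-censored recurrence-free survival (RFS) after
curative liver-tumor resection: for each subject a follow-up time in months
and an indicator of whether recurrence was observed at that time. Expression
comes from two-color microarrays as log2(Cy5/Cy3) ratios against a common
reference channel.

1. **Preprocessing.** `log_ratio()` extracts M = log2(Cy5/Cy3) and an
   *availability* mask (an entry is available when neither channel is
   saturated nor below the limit of quantification). `normalize_lowess()`
   removes the smooth intensity-dependent dye bias by subtracting, per
   sample, a locally weighted regression of M on the mean log intensity
   A = (log2 Cy5 + log2 Cy3)/2. `availability_filter()` drops genes
   available in fewer than 70% of samples. `batch_adjust()` equalizes
   hybridization batches along a discriminating direction.
2. **Ranking.** `rank_features()` scores every gene with the univariable Cox
   score — the partial-likelihood score statistic at β = 0 — and ranks by
   absolute score. The score only assumes proportional hazards locally at
   β = 0 and needs no per-gene model fit, which is what makes a 25,000-gene
   scan inside every cross-validation fold affordable.
3. **Prediction.** `build_template()` turns the top-k genes into a signed
   poor-prognosis template; `ntp_classify()` assigns the label of the nearer
   of the template and its negation under cosine distance. Cosine distance
   makes the call scale-invariant in the profile.
4. **Validation.** `loocv_predict()` re-derives the signature inside every
   leave-one-out fold (ranking, template, and marker z-scoring statistics
   all come from the n−1 training samples), so the held-out label is
   untouched by its own survival record. `sweep_signature_size()` scans
   signature sizes up to 200, assesses each size's cross-validated labels by
   the log-rank test and the misclassification rate, and picks the smallest
   k attaining the minimal p-value.
5. **Effect size.** `cox_fit()` (Newton–Raphson on the Breslow partial
   likelihood, Wald intervals) expresses the predicted class — or any
   clinical covariate — as a risk ratio with a 95% CI, the presentation
   used in clinical prognostic-marker tables.

The log-rank p-value at the *chosen* k is still selected over the sweep; the
package reports the per-k table so a reader can see the multiplicity. The
per-sample labels themselves, however, are leakage-free, which is the
property the test suite enforces by poisoning held-out records.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_fraction` (availability) | 0.70 | fraction | conventional two-color QC rule; "fewer than 70%" read as strict-less exclusion, so exactly 70% is kept |
| `span` (LOWESS) | 0.30 | fraction of probes | common M-vs-A practice; large enough to be stable, small enough to track a one-period sinusoidal bias |
| LOWESS robustness iterations | 3 | — | guards the trend against differentially expressed outliers |
| `k_max` | 200 | genes | cap on signature size in the sweep |
| `ties` (Cox) | `"breslow"` | — | closed-form testable; Efron available as an option |
| `cutoff_months` (late recurrence) | 12 | months | separates likely de-novo tumors in the cirrhotic liver from early metastatic regrowth |
| `n_perm` (SAM) | 1000 | — | permutation resolution of the FDR = 0 rule |
| set-score `method` | `"mean_z"` | — | reduction-testable (singleton sets ≡ genes); GSA `"maxmean"` offered |

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis assumes:

* ~25,000 transcripts × ~44 subjects at the defaults (tests and the
  acceptance script scale down to 2,000 × 60 or smaller to keep runtimes in
  seconds-to-minutes; those sizes are stated in each test);
* per-gene standard-normal log-ratios plus per-batch additive shifts
  (`batch_shift_sd`, default 0.3 log2 units);
* a planted prognostic module of `n_signature_genes` genes. The module is
  **co-expressed**: members share a latent factor with intra-module
  correlation `rho_signature` (default 0.5), sign-aligned with their
  coefficients, marginals still N(0, 1). This matters: were the planted
  genes mutually independent, each gene's *marginal* hazard association
  would be attenuated by the unexplained variation of the other members
  (a frailty effect of order 1/√k), and no ranking procedure could recover
  the signature at realistic cohort sizes. Real prognostic signatures are
  coherent transcriptional programs, which is the situation the generator
  reproduces;
* exponential recurrence times with per-sample hazard
  `baseline_hazard · exp(Σ β_g x_gs)` — the simplest model consistent with
  proportional hazards, which is all the Cox machinery assumes;
* independent uniform administrative censoring whose horizon is solved
  numerically so the expected censored fraction equals `censor_rate`
  (default 0.30). Follow-up length and censoring law are parameters, not
  facts about any particular cohort;
* probe-level missingness at `missing_rate` and ordinal clinical covariates
  (stage I–IV, diameter, tumor count) generated by thresholding a noisy copy
  of the linear predictor, so multivariable analyses have a known
  positively-correlated confounder structure.

`generate_two_channel()` adds the raw-intensity layer: mean log intensities
uniform over the scanner's usable range, a smooth sinusoidal dye bias of
amplitude `dye_bias_amplitude`, and saturation/below-LOQ flags at the range
extremes.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: probe sequence effects, spatial artifacts,
dye-swap designs, non-proportional hazards, informative censoring,
dependence between missingness and expression level, and cohort-specific
clinical correlation structure. Results on synthetic cohorts validate the
*machinery*, not any biological claim.

## Numerical choices and degenerate inputs

* **Ties.** Breslow everywhere: tied events share a risk set and contribute
  separately. This makes the score statistic and the partial likelihood
  explicitly codable for the finite-difference oracles in the tests.
* **Missing expression.** A gene's Cox score is computed on the sub-cohort
  where the gene is available (risk sets restricted accordingly); no
  imputation inside the statistic. SAM excludes missing entries pairwise.
  Direction-finding for batch adjustment imputes to gene means, for the
  direction only.
* **Zero-variance genes** score 0 with a degeneracy flag and rank last.
  Ties in |score| break lexicographically by gene id so rankings are
  deterministic.
* **NTP ties.** A zero-norm profile or an exactly orthogonal one is an
  undecidable case; it is resolved conservatively to "good" and flagged.
* **Marker standardization** uses training-fold mean/SD (z-scores). A
  marker with zero training variance yields an undefined z and is dropped
  from the distance for that sample. Per-sample rank standardization was
  considered and rejected as the default because it breaks the exact
  singleton-set reduction identity used to test the gene-set layer.
* **Cox fitting** uses step-halving Newton–Raphson; non-convergence in 100
  iterations errors with the gradient norm, and a coefficient path escaping
  |β| > 20 is reported as monotone likelihood (perfect separation) with
  advice to penalize rather than silently returning a huge risk ratio.
* **DWD.** No convex-cone solver is assumed: the published objective (sum of
  reciprocal margins plus penalized slacks) is minimized through its smooth
  equivalent loss V(u) = 1/u for u ≥ 1/√C and 2√C − Cu otherwise, by BFGS in
  the SVD-reduced sample space (the optimal direction lies in the span of
  the data), with C = 100/median²(between-group distance) and the
  mean-difference direction as the start. `mean_shift` is the closed-form
  alternative; both subtract centered per-batch mean projections so
  gene-wise grand means are preserved, and batches merge successively in
  label order (the order is logged).
* **"FDR = 0" in SAM** is the largest symmetric cut with zero *median*
  permuted exceedances, which reduces to cutting at the median over
  permutations of max|d*|. The fudge factor s0 follows the standard recipe:
  the s-quantile minimizing the coefficient of variation of windowed MADs
  of d.
* **Normalization order.** LOWESS is fitted before the availability filter
  freezes the gene list (normalize first, filter second); the alternative
  order changes only which probes inform the trend, not the retained values.

## Known limitations

* **The error-rate floor.** The misclassification rate compares the NTP
  label against observed recurrence status (event vs censored — the only
  labelling available for every subject; a recurrence-within-horizon
  alternative is exposed via `horizon_months`). The cosine rule splits an
  unimodal cohort near its median, so when the event fraction is far from
  one half the error rate is bounded below by the mismatch between the two
  proportions — at 30% censoring the floor is about 0.2 *even for a perfect
  risk ordering*. The log-rank p-value, which is threshold-free, is the
  meaningful recovery measure in that regime; the error rate is reported
  because the field reports it.
* **Selection over k.** The minimum-p choice of signature size is not
  multiplicity-corrected; on pure-noise matrices the minimum over a sweep
  follows the uncorrected null and should not be read as significant.
* **Gene-set universes are not canonical.** Any GMT can be supplied and a
  synthetic collection generator is included, but count-level claims about
  any particular published set universe are not reproducible from a
  collection's size alone.
* **Accession-scale counts** (e.g. how many transcripts survive the 70%
  filter on a specific deposited dataset) depend on the vendor's extraction
  settings and require the raw download; the package tests the filtering
  *rule*, not any dataset-specific count.
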