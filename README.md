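# survsig

Discovery and honest cross-validation of prognostic gene-expression
signatures for right-censored recurrence-free survival (RFS), in the style
used for hepatitis-C-associated hepatocellular carcinoma cohorts profiled on
two-color microarrays. The package is aimed at computational biologists who
want a fully testable, self-contained version of this classic signature
discovery workflow: every stage — from raw two-channel intensities to the
cross-validated Kaplan–Meier split — is an exported function, and a seeded
synthetic-cohort generator plants a known signature so the whole pipeline can
be validated without any external data.

## What it computes

**Feature ranking by the univariable Cox score.** For gene *g* with values
*x*, the partial-likelihood score statistic at β = 0,

    score(g) = U(0) / sqrt(I(0)),
    U(0) = Σ_events ( x_i − mean of x over the risk set at t_i ),
    I(0) = Σ_events var of x over the risk set at t_i,

with Breslow handling of ties. Genes are ranked by |score|; the sign says
whether high expression goes with earlier recurrence.

**Nearest template prediction (NTP).** The top-*k* genes form a signed
template *t* ∈ {−1, +1}^k (the poor-prognosis prototype). A sample with
standardized marker profile *v* is labelled by the closer of *t* and −*t*
under the cosine distance d(v, t) = 1 − v·t / (‖v‖‖t‖).

**Leave-one-out cross-validation with per-fold re-derivation.** For each
held-out sample the ranking, the template, and the marker z-scoring
statistics are recomputed from the remaining samples only, so the reported
log-rank p-value and error rate (fraction of subjects whose predicted
poor/good label disagrees with their observed recurrence status) carry no
selection leakage. `sweep_signature_size()` scans k ≤ 200 and picks the
strongest signature with the fewest genes.

Around this core: LOWESS intensity normalization of log2(Cy5/Cy3) ratios,
the 70% availability filter, distance-weighted-discrimination batch
adjustment, SAM-style permutation differential expression with the FDR = 0
rule, per-sample gene-set scores (mean-z and GSA maxmean) feeding the same
NTP machinery, Kaplan–Meier/log-rank primitives, and a Newton–Raphson Cox
proportional-hazards fitter for risk-ratio tables.

## Worked example

```r
library(survsig)

cfg    <- synthetic_config(n_samples = 44, n_genes = 2000,
                           n_signature_genes = 20, beta_signature = 1.2,
                           censor_rate = 0.3, seed = 11)
cohort <- generate_cohort(cfg)
scan   <- generate_two_channel(cfg, cohort)

expr <- log_ratio(scan)                         # log2(Cy5/Cy3) + availability
expr <- normalize_lowess(expr, scan, span = 0.3)
expr <- availability_filter(expr, min_fraction = 0.7)
expr <- batch_adjust(expr, method = "dwd")
expr
#> expr_matrix: 2000 genes x 44 samples, 2 batch(es), 95.2% available

cv <- sweep_signature_size(expr, cohort$survival, k_values = c(2:20, 25, 30))
cv
#> LOOCV nearest-template sweep over 21 signature sizes
#> chosen k = 17: log-rank p = 2.151e-10, error rate = 0.136

sig <- as.numeric(cv$chosen_labels == "poor")
cox_fit(matrix(sig, ncol = 1, dimnames = list(NULL, "rfs_signature")),
        cohort$survival)
#> Cox proportional-hazards fit (breslow ties), n = 44, events = 30
#>       variable risk_ratio         ci p_value
#>  rfs_signature      12.61 4.76-33.36 3.3e-07
```

The chosen 17-gene signature separates the cross-validated poor and good
classes at log-rank p ≈ 2×10⁻¹⁰ with a 13.6% error rate, and the predicted
poor-prognosis class carries a 12.6-fold recurrence risk ratio; 16 of the 17
chosen markers are genes the generator actually planted. `run_pipeline()`
wraps the same stages end to end and writes the sweep table, per-sample
labels, Kaplan–Meier curves, Cox risk-ratio tables, a heat-map-ready matrix
and PCA coordinates into a run directory with a JSON stage log.

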