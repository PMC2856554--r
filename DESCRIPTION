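Package: survsig
Title: Gene Expression Signatures of Recurrence-Free Survival by Nearest
    Template Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and cross-validation of prognostic gene expression
    signatures for right-censored recurrence-free survival, in the style used
    for hepatocellular carcinoma cohorts profiled on two-color microarrays.
    Implements preprocessing of two-channel scans (log-ratio extraction, LOWESS
    intensity normalization, availability filtering, distance-weighted
    discrimination batch adjustment), the univariable Cox score statistic for
    feature ranking, nearest template prediction with signed marker templates
    embedded in leave-one-out cross-validation, signature-size sweeps,
    SAM-style permutation differential expression with the FDR = 0 rule,
    gene-set-level prediction (mean-z and maxmean set scores), Kaplan-Meier
    and log-rank primitives, full Cox proportional-hazards fitting for risk
    ratios, and a seeded synthetic-cohort generator that plants a survival
    signature so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
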