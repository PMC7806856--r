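Package: cytocascade
Title: Urinary Cytokine Biomarker Panels and a Screen-Confirm Diagnostic Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplex urinary cytokine/chemokine panels in
    lower urinary tract disease cohorts (interstitial cystitis/bladder pain
    syndrome, overactive bladder, controls). Implements per-group 3-SD outlier
    exclusion and below-detection-limit flagging, group summaries with one-way
    ANOVA and post hoc testing, per-marker ROC diagnostics with Youden-optimal
    midpoint cutoffs and full confusion-matrix metrics, covariate-adjusted
    logistic odds ratios on per-unit concentration scales, and a hierarchical
    screen-then-confirm diagnostic cascade. Includes a moment-matched lognormal
    synthetic cohort generator with ground-truth outlier injection for
    end-to-end validation, and rate-to-count consistency oracles linking printed
    sensitivity/specificity to predictive values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
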