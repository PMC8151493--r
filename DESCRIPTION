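Package: lactocurve
Title: Longitudinal Metabolic Biomarker Profiling and Prognostic
    Classification of Hyperketonemia in Transition Dairy Cows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal serum biomarker panels
    (beta-hydroxybutyrate, non-esterified fatty acids, total bilirubin,
    aspartate aminotransferase) in dairy cows across the transition
    period.  Provides cohort filtering and hyperketonemia / subclinical
    ketosis case labelling, mixed-effects natural cubic spline profile
    models fitted by maximum likelihood with staged likelihood-ratio
    comparisons, per-interval group tests, onset incidence and empirical
    cumulative distribution summaries, prognostic feature extraction
    with ROC/AUC evaluation and cost-weighted Youden cut-point
    selection, CART cross-checks, and a synthetic-herd generator that
    reproduces the assumed statistical structure for fully reproducible
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    rpart,
    splines,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
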