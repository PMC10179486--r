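Package: metsdx
Title: Adiposity Indexes and Diagnostic Accuracy for Metabolic Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes anthropometric and cardiometabolic adiposity indexes
    (waist-to-hip ratio, waist-to-height ratio, body mass fat index,
    visceral adiposity index, cardiometabolic index), classifies metabolic
    syndrome from International Diabetes Federation criteria, and evaluates
    each index as a diagnostic marker: empirical ROC curves, DeLong
    confidence intervals and paired AUC comparisons, Youden-optimal
    cutoffs, and cutoff-level sensitivity, specificity, predictive values
    and likelihood ratios. Includes a seeded Gaussian-copula generator of
    synthetic two-group cohorts of women with severe obesity so the whole
    pipeline can be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
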