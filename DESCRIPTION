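Package: metscreen
Title: Adiposity Indexes as Screening Tools for Metabolic Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how well anthropometric adiposity and body-composition
    indexes (BMI, FMI, FFMI, TMI, WtHR, BMFI) identify the metabolic syndrome
    in women with obesity. Provides index computation from raw measurements,
    rule-based metabolic-syndrome classification (any three of five IDF-style
    components), age-standardization of each index by median (quantile)
    regression on the log scale with age-specific threshold curves, ROC
    analysis with DeLong variance and paired comparison of correlated AUCs,
    Youden-index cutoff selection, the full diagnostic-metric suite
    (sensitivity, specificity, PPV, NPV, likelihood ratios), supporting
    association statistics, and a calibrated synthetic-cohort generator so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
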