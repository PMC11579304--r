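Package: vapcea
Title: Decision-Tree Cost-Effectiveness Analysis of Short-Course Antibiotics
    for Ventilator-Associated Pneumonia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trial-based economic evaluation of an individualised
    short-course antibiotic strategy for ventilator-associated pneumonia
    (VAP) versus usual care, from the health-system perspective in Nepal,
    Singapore, and Thailand. Provides a synthetic patient-level trial data
    generator, multiple imputation of missing costs by chained equations
    with predictive mean matching (plus random-forest, simple-mean, and
    complete-case alternatives) pooled by Rubin's rule, country-adjusted
    outcome models (logistic regression for event probabilities, Tobit
    regression for length of stay right-censored at 60 days), a decision
    tree yielding incremental cost-effectiveness ratios and incremental
    net monetary benefits, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, nine one-way scenario
    analyses, and value-of-information analysis (EVPI and regression-based
    EVPPI with a nested Monte Carlo reference estimator).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    randomForest,
    mgcv,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
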