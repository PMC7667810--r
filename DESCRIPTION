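Package: plannsurv
Title: Partial Logistic Neural Networks for Discrete-Time Survival Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time survival prediction with partial logistic
    artificial neural networks (PLANN) for right-censored data. Exact
    follow-up times are transformed to a person-period (long) format over a
    grid of non-overlapping time intervals treated as separate indicator
    inputs; a feed-forward network with one or two hidden layers estimates
    the conditional hazard of each interval and survival curves follow by
    the product-limit identity. Includes connection-weight (Garson) relative
    importance for one- and two-hidden-layer networks with factor-level
    aggregation, an evaluation stack (Harrell concordance index, inverse
    probability of censoring weighted Brier score, Integrated Brier Score,
    reverse Kaplan-Meier follow-up, decile calibration against Kaplan-Meier),
    Cox proportional-hazards baselines (full fit, group-wise backward
    elimination, LASSO tuned by cross-validated partial likelihood), seeded
    synthetic survival cohort generators, and a split-sample / 5-fold
    grid-search tuning workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
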