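Package: ershap
Title: Confounder-Adjusted Exposure-Response Analysis with Boosted Trees
    and SHAP Attributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-stage (induction/maintenance) randomized
    clinical trial with latent health status, confounded drug exposure and
    known ground-truth log-odds marginal effects, and provides the machine
    learning workflow needed to recover those effects without bias:
    causal-diagram-driven variable selection, gradient-boosted tree
    classifiers, exact TreeSHAP attributions in the log-odds domain,
    k-fold out-of-sample prediction, sequential model-based (Bayesian)
    hyperparameter tuning, bootstrap (sampling with replacement)
    confidence intervals for attributions with out-of-bag evaluation,
    decile-binned dependence summaries, and reliability/calibration
    diagnostics based on Poisson-binomial intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xgboost,
    ranger,
    lhs,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
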