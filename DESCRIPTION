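Package: sncstm
Title: G-Estimation of Structural Nested Cumulative Survival Time Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Structural Nested Cumulative Survival Time Models (SNCSTMs)
    for survival outcomes with time-varying confounding by g-estimation, using
    only standard generalised linear model machinery. A cohort with repeated
    exposure and confounder measurements is expanded into pseudo-individuals on
    a fine time grid; causal blip parameters are then estimated by solving
    gamma log-link score equations in which the single covariate is the
    residual from a canonical propensity-score regression. Supports effect
    modification by measured history, parameter sharing across visits,
    inverse-probability-of-censoring weighting for covariate-dependent
    dropout, bootstrap standard errors, counterfactual survival curves under
    exposure removal, and a synthetic-cohort simulator with coupled
    counterfactual failure times for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
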