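Package: accumimic
Title: Evidence-Accumulation Models of Deadlined Value-Based Choice and
    Model-Mimicry Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian estimation of drift
    diffusion models with static or linearly collapsing decision bounds for
    two-alternative value-based choice under a response deadline. Includes a
    synthetic task-design generator with orthogonalised overall-value and
    value-difference regressors, exact Wiener first-passage-time likelihoods
    and a deterministic solver for collapsing bounds, a leaky competing
    accumulator simulator, a registry of value-regression model variants,
    deviance information criterion model comparison, Gelman-Rubin
    convergence diagnostics, posterior predictive checks, parameter and
    model recovery suites, and model-mimicry experiments probing when
    apparent value-driven threshold control is an artifact of model
    misspecification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
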