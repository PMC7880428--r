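Package: starlogit
Title: Bayesian Geo-Additive Logistic Regression for Pooled Household Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structured additive regression (STAR) for clustered binary
    outcomes pooled across multiple household surveys. Implements the
    logit model with an intrinsic Gaussian Markov random field (ICAR)
    prior for structured spatial effects, iid Gaussian unstructured
    region effects, Bayesian P-splines with second-order random-walk
    penalties for smooth covariate and period effects, and space-time
    interaction terms. Posterior inference uses Metropolis-Hastings
    block updates with iteratively weighted least squares (IWLS)
    proposals and conjugate inverse-gamma updates for variance
    parameters. Model assessment via the deviance information criterion
    (DIC), global Moran's I clustering tests (analytic and permutation),
    posterior odds ratios, per-region predicted prevalence and
    credible-interval significance maps. Ships a synthetic-data
    generator that emulates the pooled multi-survey girl-level data
    structure so the full pipeline is testable without restricted
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
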