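Package: jmels
Title: Joint Mixed-Effects Location-Scale Models for Repeated Exposures and Distal Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits joint mixed-effects location-scale models for longitudinal
    exposures measured repeatedly within clinic visits within individuals,
    in which both the mean trajectory and the log of the within-individual
    (visit-to-visit) variance carry fixed covariate effects and individual
    random effects, and the individual random effects are shared as
    predictors of a later individual-level outcome. Provides Bayesian
    estimation by a blocked Gibbs/adaptive-Metropolis sampler with
    convergence diagnostics, a two-stage comparator known to be biased,
    an exact-model synthetic data generator with latent truth for
    calibration studies, Gauss-Hermite and Monte-Carlo marginal-likelihood
    oracles for testing, percentage-change reporting transforms, and
    residual-based outlier screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    jsonlite,
    yaml,
    pracma,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
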