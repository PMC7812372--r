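Package: audaging
Title: Simulation and Robust Bayesian Analysis of Auditory Temporal-Processing Studies Across the Adult Lifespan
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and analysing psychophysical studies of
    age-related change in auditory temporal processing. Implements the
    updated maximum-likelihood (UML) Bayesian adaptive procedure with
    four-sweetpoint stimulus placement, classical transformed up-down
    staircases, post-hoc psychometric-function refitting by MCMC with a
    fixed guess rate and free lapse rate, derived participant scores
    (cumulative noise-exposure units, consonance preference from dyad
    ratings, cognitive principal components, questionnaire means), robust
    mixed-effects Bayesian regression with Student-t residuals and
    heavy-tailed shrinkage priors, and a synthetic-cohort generator that
    reproduces the predictor correlation structure of a cross-sectional
    ageing study so that the whole pipeline can be exercised end to end
    on simulated listeners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
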