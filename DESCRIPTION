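Package: carecast
Title: Multi-State Markov Forecasting of Elderly Health and Nursing-Staff Demand
Version: 0.1.0
Authors@R:
    person("carecast", "developers", email = "carecast@example.org", role = c("aut", "cre"))
Description: Tools for forecasting long-term-care workforce demand from
    two-wave panel data on elderly health. Health is graded into four
    living states (healthy, mild, moderate and severe disability) plus an
    absorbing death state. Age-stratified transition probability matrices
    are estimated from panel data by empirical cell proportions and by a
    multinomial logit model fitted by maximum likelihood, with Wald or
    bootstrap confidence limits. A discrete-time Markov cohort model
    projects a baseline census population forward in fixed-length steps
    with cohort aging, and the human-population-ratio method converts the
    projected state-specific populations into nursing-staff demand under
    configurable staffing schedules. Validation against a later observed
    wave uses a chi-square goodness-of-fit test; uncertainty is quantified
    by confidence-bound perturbation of the matrices and by Dirichlet
    Monte Carlo resampling. A synthetic data generator emulating the
    structure of two-wave longitudinal ageing surveys makes the whole
    pipeline testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
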