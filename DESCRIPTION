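Package: timecarry
Title: Serial Dependence and Carryover Analysis for Temporal Bisection
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying trial-to-trial carryover effects in the
    temporal bisection task (partition method). Generates path-guided,
    first-order counterbalanced de Bruijn trial sequences over seven
    log-spaced sub-second durations plus a null label; simulates a
    Bayesian-heuristic ideal observer that compares noisy duration
    percepts against a leaky, exponentially weighted geometric-mean
    memory prior under a per-trial uncertainty threshold (with four
    reduced model variants); fits condition-wise logistic psychometric
    functions (bisection point, difference limen, coefficient of
    variation, bootstrap threshold intervals); computes decision-bias and
    perceptual-carryover indices, reaction-time matrices and cohort
    correlations; recovers observer parameters by Monte Carlo grid
    search with RMSE matching; and generates fully synthetic participant
    cohorts so the entire pipeline is testable without human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
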