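Package: restlessbandit
Title: Simulation, Model Fitting and Choice Classification for the
    Four-Armed Restless Bandit Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the explore-exploit trade-off in the
    four-armed restless bandit task. Generates decaying Gaussian
    random-walk payout schedules, simulates delta-rule and Kalman-filter
    (Bayesian) learners under softmax choice rules with exploration and
    perseveration bonuses, fits the eight resulting model variants to
    trial-level choice data by multi-start MAP with Laplace posterior
    summaries or by MCMC, compares models by information criteria,
    classifies every choice as exploitative, directed-exploratory or
    random-exploratory, computes model-free behavioural summaries, and
    builds synthetic patient cohorts with group-shifted decision
    parameters for parameter- and model-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lhs,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
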