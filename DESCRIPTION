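Package: pavarb
Title: Pavlovian-Instrumental Arbitration Models for Go/NoGo Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, maximum-likelihood fitting and random-effects
    Bayesian comparison of learning models for the orthogonalized Go/NoGo
    task, in which stimulus valence (win/avoid) is crossed with the required
    action (go/nogo). Implements a heuristic reinforcement-learning model
    with a fixed Pavlovian bias, a Fixed Bayesian model with a constant
    Pavlovian weight, and an Adaptive Bayesian model in which the weight
    tracks the inferred controllability of outcomes through a trial-by-trial
    log-odds update. Includes a task simulator, per-subject model fitting
    with BIC model evidence, group-level Bayesian model selection with
    protected exceedance probabilities, model-based behavioral analyses
    (go bias by Pavlovian-weight quantile, early/late go bias, confound
    correlations with JZS Bayes factors, expected-accuracy confidence
    proxy), and parameter/model recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
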