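Package: beliefrl
Title: Belief-State Reinforcement Learning Models of Dopamine Reward
    Prediction Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of dopamine reward
    prediction errors (RPEs) under hidden-state uncertainty in a blocked
    Pavlovian conditioning task. Provides a task simulator (alternating
    small/big reward blocks with rare intermediate-reward probe blocks), a
    trial-level standard reinforcement-learning model and a family of
    belief-state models in which reward expectations are computed on a
    Bayesian posterior over hidden block identities, a synthetic-data
    generator for per-mouse dopamine and anticipatory-licking datasets, a
    fiber-photometry dF/F processing pipeline, bounded multi-start
    maximum-likelihood fitting of the models to condition-averaged dopamine
    responses, model comparison by BIC and random-effects Bayesian model
    selection (exceedance and protected exceedance probabilities), and the
    exact Wilcoxon signed-rank test and correlation/polynomial-fit
    statistics used to summarise the results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
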