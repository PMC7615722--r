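Package: habitkit
Title: Simulation, Model Fitting and Habit Scores for Frequency-Based Habit Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying frequency-based habit formation in value-based
    decision making. Generates deterministically seeded trial schedules for a
    rewarded stimulus-pair learning task, an unrewarded instructed-choice task
    and a two-stage sequential Markov decision task; simulates choices from
    reinforcement-learning, choice-kernel and hybrid model-based/model-free
    agents; fits those models by multi-start maximum likelihood with AIC/BIC
    model comparison and random-effects Bayesian model selection (exceedance
    probabilities); computes the per-participant habit scores used across
    devaluation, contingency-degradation and frequency paradigms, plus habit
    questionnaire scores; and provides analytic noncentral-t power utilities.
    A synthetic-cohort generator makes parameter- and model-recovery studies
    reproducible without any participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
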