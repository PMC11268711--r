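Package: cbdm
Title: Hierarchical Bayesian Modelling of Effort- and Delay-Based
    Cost-Benefit Decision-Making Under Drug Manipulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for within-subject
    pharmacological studies of cost-benefit decision-making. Generates
    binary-choice task designs in which a high-reward/high-cost option
    competes with a low-reward/low-cost option (grip-force effort or
    monetary delay as the cost), simulates cohorts from subjective-value
    discounting models (linear, parabolic, hyperbolic, exponential) with
    softmax choice stochasticity and per-drug additive shift parameters,
    and estimates the models with hierarchical Bayesian MCMC (JAGS).
    Includes PSIS-LOO model comparison across discounting forms,
    posterior-predictive model validation and parameter recovery,
    hierarchical Bayesian logistic regression of choice on drug, reward
    and cost, Bayesian correlation of discounting parameters across
    tasks, and convergence diagnostics (split-chain r-hat, highest
    density intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
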