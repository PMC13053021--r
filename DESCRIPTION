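Package: refprodsim
Title: Simulation and Analysis of Reference-Production Experiments with
    Psychophysically Calibrated Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and testing referential-communication
    (director-task) experiments end to end without human participants.
    Constructs perceptually smooth stimulus continua in CIELAB colour space
    and in modal impact-sound parameter space, runs interleaved dual
    adaptive staircases to extract high- and low-discriminability stimuli
    per simulated participant, generates counterbalanced director-task
    trials for two experiment designs, simulates logistic-psychometric
    observers and logit-linear speakers with by-subject random intercepts,
    and analyses the resulting responses with Bayesian mixed-effects
    logistic regression (MCMC via JAGS), model comparison, psychometric
    curve fitting, and bootstrapped summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    jsonlite,
    purrr,
    rjags,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
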