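Package: prosamp
Title: Bayesian Proactive Sampling Simulator for Value-Based Choice
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates two-alternative value-based decisions as Bayesian
    proactive information sampling. Each item's subjective value is
    estimated from noisy Gaussian samples, with the non-fixated item's
    evidence mean-discounted and variance-inflated; posterior beliefs are
    updated conjugately, with a multiplicative forgetting factor expanding
    uncertainty about the non-fixated item. A decision fires when the
    probability of choosing the higher-valued item exceeds a linearly
    collapsing confidence threshold, and gaze switches are drawn from a
    logistic policy on the posterior uncertainty ratio. Includes a
    synthetic rating/pairing experiment generator, a summary-statistics
    pipeline for choice and fixation patterns (psychometric curves,
    fixation-duration analyses, last-fixation surfaces), and a minimal
    attentional drift-diffusion baseline driven by fixation schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
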