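Package: changedet
Title: Bayesian and Suboptimal Observer Models for Orientation Change
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and fitting of Bayesian observer models for visual
    orientation change detection with stimulus reliability cues.  Implements
    equal-precision and variable-precision (doubly stochastic, gamma-mixture)
    encoding of orientations with von Mises measurement noise, the full
    taxonomy of fourteen observer models combining four assumptions about
    encoding precision with optimal and Max integration rules (plus decision
    noise variants), Monte-Carlo computation of response probabilities per
    trial type, grid-based maximum-likelihood fitting, and Bayesian model
    comparison by grid marginal likelihoods with log-sum-exp stabilization.
    Includes a synthetic-experiment generator, behavioral summary statistics
    (hit and false-alarm rates conditioned on reliability, psychometric
    curves), goodness of fit, and a model-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
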