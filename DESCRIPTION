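Package: avci
Title: Bayesian Causal Inference Models for Audio-Visual Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ideal-observer models of audio-visual spatial perception built
    around Bayesian causal inference: forced-fusion (maximum-likelihood
    estimation) cue-combination predictions, closed-form causal-inference
    likelihoods and decision rules for implicit (localization) and explicit
    (common-cause report) tasks, cumulative-Gaussian and Gaussian-curve
    psychometric fitting, maximum-likelihood model fitting with AIC and
    explainable-variance-explained model comparison, and a synthetic-observer
    simulator that reproduces the trial schedules of five behavioral
    experiments for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
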