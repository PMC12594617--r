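Package: painweights
Title: Precision-Weighted Bayesian Modelling of Cued Pain Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling trial-by-trial pain ratings in a cued
    electrical-pain paradigm as a precision-weighted combination of the
    delivered stimulation, the observed cue, and a participant-specific
    trait-like bias. Provides the cued-task trial generator, the Gaussian
    generative rating model and its collapsed likelihood, per-participant
    Bayesian inversion by MCMC with variance-to-precision transformation of
    the posterior draws, event-locked EEG window summaries with
    individualised P2 peak extraction, Spearman correlation analyses of the
    inferred weights against region-of-interest activity and covariates with
    per-window Benjamini-Hochberg correction, correlation power analysis,
    and a ground-truth synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
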