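Package: restact
Title: Rest-Activity Rhythm, Behavioral Organization and Complexity
    Analysis for Actigraphy
Version: 0.1.0
Authors@R: person("restact", "developers", role = c("aut", "cre"),
    email = "restact@example.org")
Description: Analysis pipeline for minute-epoch actigraphy recordings of
    the kind collected from collar-mounted data loggers in non-human
    primates. Implements single- and double-component cosinor fitting of
    circadian and semi-circadian rhythms, threshold-based rest/active bout
    extraction with power-law and stretched-exponential survival-curve
    fits, daytime Sample Entropy, hourly-profile group comparison by mixed
    repeated-measures ANOVA, cortisol-activity correlation reporting, and
    three-chamber social-preference scoring, together with a seeded
    synthetic-cohort generator so every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
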