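Package: cusumcurve
Title: CUSUM Learning-Curve Analysis for Surgical Outcome Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify a surgical learning curve from a chronologically
    ordered case series. Implements cumulative-summation (CUSUM) performance
    charts against predefined target levels for continuous outcomes
    (patient-reported shoulder scores, range of motion, operation time) and a
    Bernoulli CUSUM for binary complication events; ordinary least-squares
    trend fits with R-squared; reproducible segmentation of a CUSUM chart into
    learning, consolidation and mastering phases; complication classification
    and rate tables; and a seeded synthetic-cohort simulator with an
    exponential learning model so the whole pipeline can be exercised and
    validated without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
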