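Package: srtvalid
Title: Validity and Agreement of 20-m Shuttle Run VO2peak Prediction
    Equations in Children
Version: 0.1.0
Authors@R:
    person("Maintainer", "srtvalid", email = "srtvalid@example.org",
           role = c("aut", "cre"))
Description: Tools for validating field-test predictions of peak oxygen
    uptake (VO2peak) in school-age children against direct oximetry.
    Implements the arithmetic of the multistage 20-m shuttle run test
    (stage speeds, lap timing), a registry of 22 published VO2peak
    predictive equations with their original sex codings and units,
    Slaughter skinfold percent body fat, maximal-effort screening of
    gas-exchange summaries, and the full method-agreement toolkit
    (paired and Welch t comparisons, Cohen's d and Hedges' g with
    Hopkins magnitude bands, Pearson validity with standard error of
    estimate, and Bland-Altman limits of agreement with a
    proportional-bias slope). A synthetic-cohort generator calibrated
    to published group summary statistics makes every stage of the
    analysis testable without access to raw data, and a pipeline
    orchestrates the study end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
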