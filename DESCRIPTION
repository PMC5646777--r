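Package: hiberphen
Title: Hibernation Phenotyping from Body-Temperature Logger Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments subcutaneous body-temperature logger traces from
    food-storing hibernators into torpor bouts using temperature and
    duration thresholds, classifies bouts as deep, short, or short-shallow,
    derives per-individual hibernation phenotypes (bout counts, time in
    torpor, phenology, hibernator status), accounts for food-store energy
    and polyunsaturated fatty acid (PUFA) budgets from diet composition
    constants, and fits the associated statistical model suite (linear
    mixed models with Type III tests, post-hoc interaction contrasts,
    AICc-based predictor reduction, and classical two-sample tests).
    Includes a trace and cohort simulator with known ground truth so that
    every pipeline stage can be validated by recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nlme,
    car,
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
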