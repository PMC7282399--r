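Package: ndastandards
Title: Construction of Prescriptive Neurodevelopmental Standards from the
    INTER-NDA Instrument
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build international, prescriptive neurodevelopmental
    standards for 2-year-old children from the 37-item INTER-NDA instrument:
    ordinal item scoring into 0-100 standardised scaled domain scores, a
    WHO-style prescriptive exclusion cascade with a full audit trail,
    distribution-free pooled centile estimation with the Harrell-Davis
    estimator, direction-aware normality thresholds and three-zone screening
    classification, cohort-normality validation (between-site variance share,
    sex comparison, vision centiles, motor-milestone windows), and a seeded
    multi-site synthetic-cohort generator with known ground truth for every
    downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
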