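Package: nvhap
Title: Semi-Automated Surveillance of Non-Ventilator Hospital-Acquired
    Pneumonia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tooling for rule-based, semi-automated surveillance of
    non-ventilator hospital-acquired pneumonia (nvHAP) from routine
    electronic health record extracts. Implements a configurable one- to
    five-indicator preselection algorithm (chest radiology procedure,
    radiology report text rule, leukocyte count, body temperature,
    intubation), a language-configurable negation rule for radiology
    reports, ECDC-style pneumonia confirmation with the nvHAP/iHAP/VAP
    split, validation statistics (sensitivity with exact confidence
    intervals, review workload, number needed to screen, sample-size
    planning, enriched validation cohorts), and a seeded synthetic
    hospital generator with ground-truth pneumonia episodes for
    end-to-end validation of a surveillance setup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
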