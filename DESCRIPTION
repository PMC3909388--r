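Package: cohortflow
Title: Code-Based Cohort Assembly for Matched Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles matched case-control cohorts from coded electronic
    health record (EHR) data the way hospital informatics teams do it in
    practice: boolean ICD-9-CM/CPT code-set phenotype queries over a billing
    event layer, deterministic eligibility screening against a clinical truth
    layer (an in-silico stand-in for manual chart review), automated
    demographic matching followed by randomized sequential review of control
    candidates until a target matching ratio is reached, and CONSORT-style
    attrition tabulation. Includes a calibrated synthetic-EHR generator for a
    pediatric gastrostomy-tube-fed population with incident kidney stones, so
    the full pipeline is testable and reproducible without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
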