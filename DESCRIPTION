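Package: rorscreen
Title: Disproportionality Screening of Spontaneous Adverse-Event Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds case-level analysis tables from JADER-style spontaneous
    adverse-event reporting databases (demographics, drug and reaction tables),
    screens every drug for disproportionate reporting of a target adverse event
    with reporting odds ratios (ROR), Woolf confidence intervals and two-sided
    Fisher exact tests, visualizes screens as volcano plots, adjusts for patient
    covariates with multiple logistic regression, and runs stratified
    administration-route and co-treatment analyses. Includes a synthetic
    report-database generator with known ground truth so every pipeline stage is
    testable without access to a real pharmacovigilance download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
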