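Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance analysis of spontaneous
    adverse-event report databases in the four-table JADER layout (demo,
    drug, reac, hist): record cleaning, deduplication and case linkage;
    exposure, event and comorbidity definitions via MedDRA preferred-term
    sets; reporting odds ratios and BCPNN information components with
    exact confidence intervals and a dual signal criterion; age-stratified
    subgroup tables; multivariable logistic factor analysis with
    separation handling; and time-to-onset summaries. Includes a
    synthetic-database generator with known ground truth so every stage
    is testable without access to the raw regulatory extract.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
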