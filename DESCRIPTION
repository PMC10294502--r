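Package: mcdrules
Title: Association-Rule Analysis of Multiple Chronic Diseases in Health-Panel Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multimorbidity (multiple chronic diseases, MCD)
    in health-panel survey cohorts with association-rule mining. Derives binary
    chronic-condition profiles (14 grouped KHPS conditions plus BMI-based
    obesity) from per-participant records, stratifies participants by regular
    exercise habit, mines association rules with a level-wise Apriori
    implementation under support/confidence/lift thresholds, removes symmetric
    duplicate pair rules, and compares rule sets between exercise strata with
    per-disease appearance counts and a percentage-increase statistic. Includes
    Table-1-style descriptive statistics, a disease co-occurrence network
    summary, and a synthetic-cohort generator with plantable pairwise
    associations for validation without access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    yaml,
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
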