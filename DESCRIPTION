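Package: icfmatch
Title: Need-Based Matching of Patient Functional Limitations to Healthcare
    Services with the ICF
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Content-based recommendation of healthcare services for
    multimorbid patients. Functional limitations derived from common
    geriatric assessments (Timed Up-and-Go, MMSE, clock-drawing test,
    Geriatric Depression Scale, IADL) are coded in the WHO International
    Classification of Functioning, Disability and Health (ICF) with 0-4
    severity qualifiers, and matched against the ICF-coded treatment
    targets of a service catalogue by need-weighted taxonomic proximity
    on the ICF mono-hierarchy. Includes tools for evaluating recommender
    output against expert-panel (Delphi) rating matrices: per-rater
    counts, majority consensus, the asymptotic Wilcoxon signed-rank test
    and Cohen's effect size, plus a seeded synthetic-cohort generator
    for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
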