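Package: infantri
Title: Reference Intervals for Infant Liver Biochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates age- and feeding-stratified clinical laboratory
    reference intervals from per-infant cohort data. Implements the
    CLSI-style nonparametric rank estimator, the robust biweight
    (Horn-Pesce) estimator and direct percentile estimation for heavily
    left-censored analytes, each with 90% bootstrap confidence intervals;
    modified Dixon (one-third-range) outlier screening; Harris-Boyd
    partition testing; and Wilcoxon rank-sum comparisons of feeding
    groups with censoring-aware tie handling. Ships a synthetic cohort
    generator that emulates infant liver-panel data (log-normal analytes,
    limit-of-quantitation censoring, CRP contamination) so the whole
    pipeline can be exercised and validated without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
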