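Package: ebvar
Title: Day-to-Day Variability and Measurement Duration for Energy Balance
    Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the day-to-day variability of free-living energy
    expenditure, physical activity and energy intake outcomes recorded as
    daily subject-day tables, and derives the minimum number of monitoring
    days needed for acceptable test-retest reliability. Implements wear-time
    valid-day filtering, partitioning of total energy expenditure into
    resting, diet-induced and activity components, random-intercept mixed
    model variance decomposition on log-transformed outcomes, intraclass
    correlations with Spearman-Brown prophecy extrapolation,
    intra-individual coefficients of variation, and magnitude-based
    inference for covariate, day-of-week and measurement-order effects.
    Includes a synthetic cohort generator with the same statistical
    structure for validation by parameter recovery.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
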