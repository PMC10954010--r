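Package: cariseg
Title: CARI Food-Security Scoring and CHAID Segmentation for Household Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores household food-security surveys with the three component
    indicators of the WFP Consolidated Approach for Reporting Indicators of
    food security (CARI): the food consumption score (FCS), the proportion of
    wages allocated to food expenses (PWFE), and the livelihood coping
    strategy classification (CSI).  Combines them into the four-level Food
    Security Index (FSI), builds the CARI reporting console and the
    indicator-by-index association cross-tabs with Pearson chi-square tests,
    and segments households with a from-scratch CHAID (chi-squared automatic
    interaction detection) implementation with Kass-style category merging
    and Bonferroni-adjusted split selection.  Includes a calibrated synthetic
    survey generator so the full pipeline is testable without restricted
    survey microdata.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
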