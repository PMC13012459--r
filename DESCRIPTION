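Package: biotraj
Title: Longitudinal Blood-Biomarker Trajectory Analysis for Digital Health Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal cohorts of digital health
    platform users with repeated blood-biomarker draws, wearable activity and
    sleep data, genotypes, and engagement records. Classifies biomarker values
    into five ordinal clinical reference zones, scores baseline-to-follow-up
    improvement and optimization, quantifies the expected regression-to-the-mean
    component of observed change, computes polygenic scores from variant weight
    tables and tests stratum-dependent biomarker change, characterizes
    wearable-defined responders, and tests engagement against zone-shift
    outcomes with contingency tables. Ships a synthetic cohort generator that
    reproduces the statistical structure every stage assumes, so the whole
    pipeline is testable without external data.
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
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
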