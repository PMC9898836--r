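Package: qtscreen
Title: High-Throughput Screening of Medication Effects on the Corrected QT Interval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for screening real-world medication effects on
    the heart-rate-corrected QT interval (QTc) from electronic-health-record
    style data. Computes QTc under five correction formulas (Bazett,
    Fridericia, Hodges, Framingham, Rautaharju), applies standard ECG quality
    filters, converts pharmacy fill records into drug coverage intervals and
    classifies every (ECG, drug) pair as on- or off-medication with a washout
    and same-population eligibility rule, estimates per-drug mean QTc
    differences with percentile bootstrap confidence intervals, screens
    medication-by-covariate interactions with per-medication Bonferroni
    correction, and summarises effects by torsades-de-pointes risk class.
    Includes a synthetic cohort generator with exported ground truth so every
    stage is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
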