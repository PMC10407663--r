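Package: carbrisk
Title: Censored Pesticide-Residue Surveys and Probabilistic Dietary Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing left-censored pesticide-residue surveys and
    for probabilistic dietary risk assessment. Summarises survey records by
    detection frequency at a quantification threshold, conditional medians,
    maxima, and over-limit ratios against maximum residue limits, with
    half-LOD substitution for non-detects. Generates synthetic surveys
    calibrated to published per-food summary tables through a truncated
    lognormal residue model, so that pipelines built on undeposited survey
    data remain testable. Provides spatial-temporal association tools (annual
    series, pesticide dosage, Spearman rank correlation, rank-based group
    tests) and a Monte Carlo engine for chronic and acute hazard quotients
    across population groups, including the deterministic high-percentile
    acute intake bound used in international short-term intake estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
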