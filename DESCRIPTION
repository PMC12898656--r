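Package: speechtsp
Title: Temporal Speech Parameters of Spontaneous Speech: Extraction,
    Case-Control Statistics and ROC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the temporal analysis of spontaneous speech from
    phone-level forced alignments. Reads time-aligned token sequences
    (CTM files and Praat TextGrid interval tiers), normalizes pause
    structure, and computes the fifteen classical temporal speech
    parameters (tempi, pause occurrence rates, duration rates,
    frequencies and average durations over silent, filled and total
    pause scopes). Implements the accompanying case-control statistical
    chain -- normality-gated two-sample tests from raw data or printed
    group summaries, Cohen's d, correlation-based variable pruning,
    Bonferroni correction -- and per-variable ROC analysis with
    Hanley-McNeil standard errors and Youden-index cut-points. Includes
    a calibrated synthetic cohort generator so the full pipeline is
    reproducible without speech recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    car,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
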