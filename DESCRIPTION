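Package: resteeg
Title: Resting-State EEG Band Power, Reactivity and Coherence Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state EEG biomarkers of smoking
    status: relative spectral band power, eyes-closed versus eyes-open
    reactivity, inter-channel magnitude-squared coherence, channel-wise
    nonparametric group statistics with false-discovery-rate control, and
    bootstrap feature-covariate correlations. Includes a synthetic
    three-group EEG cohort generator with configurable ground-truth effects
    so that every stage of the pipeline can be validated by parameter
    recovery, plus readers and writers for EDF and BrainVision recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
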