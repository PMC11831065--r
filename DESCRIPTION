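Package: coherenet
Title: Resting-State EEG Coherence Networks and Edge-Wise Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state EEG functional connectivity
    based on magnitude-squared coherence. Estimates Welch auto- and
    cross-spectra per channel pair, averages coherence within canonical
    frequency bands (delta through beta2, including the alpha1/alpha2/alpha3
    sub-bands), compares every channel pair between two subject groups with
    Mann-Whitney U tests under Benjamini-Hochberg false-discovery-rate
    correction, and builds median-thresholded group connectivity graphs and
    case-deficit difference graphs. Includes a deterministic preprocessing
    chain (zero-phase band-pass filtering, kurtosis-based bad-channel
    rejection, average re-referencing, condition segmentation), a seeded
    synthetic-cohort generator with analytically computable pairwise
    coherence for validation, minimal EDF+ input/output, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
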