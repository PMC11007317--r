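Package: swatopo
Title: Sleep Slow-Wave Activity Topography and Its Association with Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing the topographic
    distribution of slow-wave activity (SWA, 0.8-4.6 Hz) in NREM sleep EEG and
    relating it to per-subject behavioral scores such as public goods game
    contribution-minus-belief prosociality scores. Provides readers and
    writers for EDF and BrainVision recordings, plain-text hypnograms,
    electrode montages and behavioral tables; zero-phase band-pass filtering,
    average re-referencing and hypnogram-aligned epoching; Hanning-windowed
    subepoch spectra, moving-average artifact screening, relative and
    log-relative SWA topographies with spherical interpolation of bad
    channels; spherical-spline surface Laplacian current source density;
    hypnogram sleep parameters and Feinberg-Floyd style sleep-cycle
    segmentation with per-cycle SWA maps; electrode-wise Pearson correlation
    mapping with suprathreshold cluster permutation correction, cluster
    summaries and partial correlations; and a seeded synthetic-data generator
    that emulates the statistical structure of a 59-channel sleep study so
    that every stage of the pipeline can be exercised and validated without
    real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
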