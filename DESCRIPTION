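Package: swdeeg
Title: Time-Frequency-Spatial Analysis of Spike-Wave Discharge EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel scalp EEG around absence
    seizures: zero-phase Butterworth band-pass and notch filtering, labelled
    1-s epoching around annotated seizure onsets, Welch power spectral
    density and per-rhythm log band power, Hilbert-phase phase-locking-value
    (PLV) synchronization matrices and thresholded binary networks,
    radial-basis scalp topography with a spatial diffusion-extent
    metric, and Kruskal-Wallis comparisons of band power and PLV across
    inter-ictal, pre-ictal and ictal states. Includes a deterministic
    generator of synthetic 16-channel spike-wave-discharge recordings
    (1/f background, posterior alpha, pre-ictal slow-rhythm elevation,
    frontal-dominant 3 Hz discharges with propagation lag) so every stage
    is testable without patient data, plus a transcribed cohort metadata
    table with summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    signal,
    generics,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
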