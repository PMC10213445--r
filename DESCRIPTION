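Package: circaeeg
Title: Circadian Rhythm Extraction and Phase Estimation from Sleep EEG/EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts circadian components from stage-scored mouse EEG/EMG
    recordings and estimates subjective circadian time from EEG spectral
    distributions. Provides per-epoch power spectra on a 0.1 Hz grid,
    stage-conditioned hourly spectral averages, first-Fourier-harmonic
    amplitude and peak-time extraction, cosinor fitting of hourly sleep
    amounts, an Otsu-threshold EMG wake override, Mardia-Watson-Wheeler
    circular two-sample tests, and a bank of regression models that map
    normalized hourly spectra onto the unit circle to decode time of day.
    A synthetic cohort generator with known injected rhythms supports
    ground-truth recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    caret,
    ranger,
    minpack.lm,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
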