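Package: tinsleep
Title: Behavioural Tinnitus Indexing and Sleep EEG Analysis for the Ferret
    Noise-Overexposure Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for noise-overexposure tinnitus studies in
    the ferret: scoring of operant silent-gap and silence-detection sessions
    with psychometric function fitting and threshold normalisation; a
    behavioural tinnitus index summing continuous-sound, gap-threshold and
    silence-detection change metrics; auditory brainstem response (ABR)
    quantification via RMS magnitudes in level-shifted response windows,
    level-response areas and automated threshold surrogates; sleep
    architecture and EEG spectral analysis (4-s epoch Hanning periodograms at
    0.25 Hz resolution, bootstrap outlier exclusion, state spectra and
    slow-wave-activity time courses); and vigilance-state-resolved auditory
    evoked response magnitudes from bootstrapped means. Includes synthetic
    data generators with known ground truth for all modalities, and minimal
    EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
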