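Package: risetap
Title: Amplitude Rise-Time Extraction and Sensorimotor Synchronization
    Analysis for Spoken Sentences
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying speech rhythm through amplitude-envelope
    landmarks and finger-tapping synchronization. Computes smoothed energy
    contours from mono speech recordings, approximates perceptual centres
    (P-centres) per syllable via the point of maximal energy rise (maxD),
    extracts amplitude rise-times and rise-slopes (with a Hilbert-envelope
    alternative), assembles per-syllable linguistic feature tables, converts
    looped finger-tap recordings into kernel-density tapping peaks, anchors
    taps to landmarks to obtain signed and absolute asynchronies, and fits
    the associated linear regression workflow (backward elimination,
    nested-model comparison, variance inflation factors, standardized
    coefficients). A synthetic-data module generates waveforms, tap trains
    and feature tables with known ground truth so the full pipeline can be
    exercised end-to-end without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
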