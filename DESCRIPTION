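Package: painfnirs
Title: Sensorimotor fNIRS Pipeline for Pressure-Pain Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable analysis pipeline for multi-channel continuous-wave
    functional near-infrared spectroscopy (fNIRS) experiments with painful and
    non-painful pressure stimulation. Converts two-wavelength light intensities
    to optical density and hemoglobin concentration changes via the modified
    Beer-Lambert law with an age- and wavelength-dependent differential
    pathlength factor, removes physiological noise with Savitzky-Golay
    filtering and short-separation regression, performs event-related epoching
    with median block averages, and runs a channel-wise nonparametric
    statistical battery (exact Wilcoxon tests, Friedman tests,
    Benjamini-Hochberg FDR) in both all-channel and responder-only modes.
    Includes heart-rate and behavioral (pressure-pain threshold) analyses and a
    seeded synthetic-data generator with known ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
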