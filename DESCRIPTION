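Package: chromodwell
Title: Single-Particle Tracking Analysis of Chromatin-Binding Dynamics and
    Citrullination Site Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for live-cell single-particle
    tracking of chromatin-binding proteins such as HP1gamma: synthetic
    movie/trajectory generation under two-state Brownian motion with
    photophysics and motion blurring, band-pass spot detection with
    brightness-weighted centroids and SNR/size gates, nearest-neighbour
    trajectory linking by optimal assignment, jump-distance diffusion
    mixture fitting with BIC model selection, residence-time
    exponential-mixture survival fitting with parametric bootstrap, and a
    binomial fragment-match PTM localization score for assigning
    citrullination sites from tandem mass spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    clue,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
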