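Package: pfcdyn
Title: Prefrontal Cortex Electrophysiology Dynamics After Psychedelic Dosing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multi-channel rat medial prefrontal cortex
    recordings in pharmaco-electrophysiology block designs (drug versus
    vehicle, rest versus task, multi-day). Implements Welch spectral
    estimation with 1/f-baseline interpolation to unmask high-frequency
    oscillations and map their depth topography, spike-sorting quality
    control and putative cell-type classification from waveform width and
    autocorrelogram rise time, firing-rate change analysis, binarized
    network-state mean-squared displacement and Lempel-Ziv complexity of
    spiking, and a nonparametric statistical layer (Scheirer-Ray-Hare,
    sign-flip permutation tests, PCA-based partial Bonferroni correction).
    Ships a synthetic-data generator that emulates the block design and drug
    effects so the full pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    graphics,
    jsonlite,
    minpack.lm,
    rhdf5,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
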