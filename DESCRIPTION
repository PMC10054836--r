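Package: episens
Title: Epithelial Barrier Impedance and Stripping-Voltammetry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-analysis chain for Transwell epithelial barrier
    monitoring with integrated electrochemical sensors. Fits the
    two-RC-element equivalent circuit of a polarized cell monolayer to
    impedance spectra by complex nonlinear least squares to extract the
    transepithelial electrical resistance (TEER) and cell-layer
    capacitance; extracts oxidation peak currents from square-wave
    anodic stripping voltammograms; fits log-linear ion calibration
    curves with correlation, relative standard deviation and limit of
    detection; and turns time-stamped apical/basolateral peak currents
    into barrier-permeability time-courses. A seeded synthetic-data
    generator emulates both instruments so the full pipeline runs and
    is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
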