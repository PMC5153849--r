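Package: odcal
Title: Calibration of Optical Density Measurements for Microbial Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for converting plate-reader optical density (OD) readings
    into microbial cell concentrations. Implements single-particle
    light-scattering calculations (exact Mie series, Rayleigh and
    anomalous-diffraction limits, detector-acceptance correction), a turbidity
    forward model covering the single- and multiple-scattering regimes,
    robust quadratic calibration-curve fitting and inversion, cross-instrument
    calibration, growth-curve conversion with growth-metric extraction, and a
    synthetic-data generator for bead dilution series, growth with changing
    cell size, and microscope field-of-view counting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
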