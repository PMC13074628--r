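Package: srswater
Title: Two-Wavelength SWIR Spatial-Ratio Estimation of Tissue Water Fraction
Version: 0.1.0
Authors@R:
    person("srswater", "maintainers", email = "srswater@example.org",
           role = c("aut", "cre"))
Description: Tools for hydration sensing with short-wave infrared (SWIR)
    diffuse reflectance at two wavelengths (1450 and 1650 nm) and two
    source-detector separations (0.45 and 0.70 cm). Provides a Monte Carlo
    photon-transport engine matched to a compact reflectance probe
    (finite LED source, aperture-limited and acceptance-cone-limited
    collection), lookup tables mapping reduced scattering to same-wavelength
    far/close spatial ratios, a semi-infinite diffusion-dipole forward model,
    a measurement-correction pipeline (dark subtraction and PTFE reference
    normalization), and a calibration-anchored bulk water-fraction sweep.
    Includes gelatin-Intralipid phantom recipe bookkeeping and a synthetic
    measurement generator for end-to-end testing without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
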