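Package: fingerppg
Title: Monte Carlo Finger Photoplethysmography and Noninvasive Glucose
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates reflectance-mode photoplethysmography at 660 and 940
    nm in a nine-layer heterogeneous finger model by voxel-based Monte Carlo
    photon-packet transport (Henyey-Greenstein scattering, Fresnel
    boundaries, Russian roulette), computes per-layer tissue optical
    properties as functions of oxygen saturation and blood glucose, sweeps a
    saturation-by-glucose grid into a synthetic training table, fits a
    gradient-boosted tree regressor mapping detected intensities and SpO2 to
    glucose, and evaluates clinical accuracy with regression metrics, Clarke
    error-grid analysis and Bland-Altman statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
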