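Package: prpsim
Title: Geometry-Based 3D Simulation of Panretinal Photocoagulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates panretinal photocoagulation (PRP) on an equal-area
    flattened model of the human retina. Builds a rotationally symmetric
    photoreceptor-density solid of revolution from an eccentricity-density
    profile, generates deterministic scatter and full-scatter laser spot
    layouts on concentric annuli, integrates the photoreceptors destroyed
    per burn, and reports the photoreceptor destruction index and the
    photocoagulation index. Includes a parametric rod-density generator
    with a packaged synthetic profile calibrated to published totals, a
    Monte Carlo integration oracle for quadrature validation, and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
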