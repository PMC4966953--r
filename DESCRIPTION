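Package: streamstress
Title: Inference of Cortical Shear Stress Driving Cytoplasmic Streaming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer the spatial distribution of shear stress at the
    cell cortex that drives cytoplasmic streaming. Quantifies intracellular
    flow fields from time-lapse image stacks by multi-pass particle image
    velocimetry with gradient-based sub-pixel refinement, simulates steady
    axisymmetric Stokes flow inside idealised cell shapes (sphere, capsule)
    with a stream function-vorticity finite-difference solver on a
    boundary-fitted grid, parametrises the cortical stress profile as a
    clamped cubic B-spline, and estimates the spline amplitudes from observed
    velocities by sampling-based Bayesian data assimilation. Includes the
    downstream pressure-field reconstruction used to compare source-pole
    pressure gradients between stress distributions, and synthetic-data
    generators so the whole pipeline is testable without microscopy data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    splines,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
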