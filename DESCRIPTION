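Package: fringe3d
Title: Phase-Shift Fringe-Projection Profilometry for Lesion Measurement on
    Curved Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software digital twin of a structured-light 3D shape
    measurement rig for gastrointestinal endoscopy research. Renders
    N-step phase-shifted sinusoidal fringe images of analytic
    stomach-like test surfaces (half-pipe jigs, protruded or depressed
    lesions, graphite marker grids), recovers wrapped phase, unwraps it
    temporally or spatially, and triangulates metric height maps.
    A measurement layer extracts cross-sectional profiles, computes
    path lengths along curved mucosal surfaces, fits virtual inferior
    base surfaces by polynomial approximation, segments lesions, and
    reports major and minor lesion diameters measured along the
    reconstructed surface. An evaluation harness replicates marker-grid
    height-accuracy and curved-surface length-accuracy experiments
    in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
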