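Package: vertebroflow
Title: Two-Phase Darcy Flow Simulation of Bone-Cement Injection in Vertebral Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-volume simulator of percutaneous vertebroplasty cement
    injection, modeled as unsteady incompressible two-phase (silicone oil/air)
    Darcy flow through a voxelized porous vertebral-body phantom. Builds
    parametric elliptical-cylinder phantoms with an impermeable cortical shell
    and an optional pedicle channel, solves an IMPES-style sequential
    pressure/saturation scheme (implicit pressure via preconditioned conjugate
    gradients, upwind saturation transport), and reports the plane-wise
    distribution metrics used to characterize cement spread: per-section area
    percentage, equivalent radius versus time, endplate and wall-ring contact,
    and whole-volume sphere-likeness.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
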