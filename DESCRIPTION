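Package: bodycomp3
Title: Three-Compartment Body Composition and Cardiovascular MRI Analysis
Version: 0.1.0
Authors@R: person("Body Composition", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-body MRI body-composition and cardiovascular
    analysis in adolescents: adipose-compartment segmentation of fat-fraction
    image stacks (background removal, fat thresholding, radial subcutaneous
    boundary tracing, compartment volume summation), QA-method pulse wave
    velocity and derived hemodynamic indices (stroke volume, ejection
    fraction, cardiac output, left-ventricular mass, total arterial
    compliance, systemic vascular resistance), LMS-based anthropometric
    z-scoring with Haycock body surface area, and a sequential-residualization
    three-compartment association model separating nonadipose, subcutaneous
    and visceral tissue contributions to cardiovascular remodeling markers.
    Includes seeded generators for phantoms, aortic flow/area waveforms and
    synthetic cohorts with known ground truth, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
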