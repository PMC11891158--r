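Package: oncosim
Title: Discrete-Event Multiscale Simulation of Solid Tumor Growth and
    Radiotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-entity, discrete-event simulator of solid (prostate)
    tumor free growth and response to fractionated external-beam radiotherapy.
    Tumor tissue is represented on a 3-D cubic mesh of geometrical cells, each
    holding a compartmental bookkeeping of biological cells by category (stem,
    limited-mitotic-potential progenitor, terminally differentiated, apoptotic,
    necrotic), cell-cycle phase and radiation-hit status, advanced on an hourly
    clock. Radiation cell kill follows the linear-quadratic model with
    oxygen-enhancement-ratio derived phase-specific radiosensitivities.
    Includes an equilibrium bootstrap for artifact-free tumor initialization,
    morphological rules for tumor expansion, shrinkage and cohesion,
    one-factor-at-a-time sensitivity analysis, and calibration of the
    linear-quadratic alpha parameter to an observed volume reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    jsonlite
Config/testthat/edition: 3
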