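Package: aneumorph
Title: Morphometry and Virtual Growth of Intracranial Aneurysm Surface Models
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for patient-specific intracranial aneurysm geometry:
    reads and writes triangulated vascular surfaces (STL, binary or ASCII),
    places a model in the neck-plane frame by a rigid transformation,
    extracts the neck curve by mesh-plane intersection, and measures the
    aneurysm size ratio (ASR), the perpendicular sac height divided by the
    perimeter-derived average neck diameter. A height-graded anisotropic
    scaling transformation deforms the sac alone, keeping the parent vessel
    and neck invariant, so that a longitudinal series of virtual growth
    models at prescribed ASR values can be generated from one geometry.
    Includes a synthetic vessel-plus-sac phantom generator with closed-form
    morphometry for validation, measurement-plane utilities, and Pearson
    correlation of ASR against plane-averaged hemodynamic summaries.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
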