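Package: adiposeg
Title: Semi-Automatic Segmentation and Volumetry of Abdominal Adipose
    Tissue from Axial T1 MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying visceral and subcutaneous abdominal
    adipose tissue (VAT, SAT) on axial T1-weighted magnetic resonance
    images and converting the resulting compartment masks into volumes
    and the VAT/SAT ratio. The segmentation pipeline normalizes slice
    intensities, extracts the torso by radial region growing, thresholds
    bright adipose voxels, separates the subcutaneous ring from internal
    visceral fat by morphological erosion, component labelling and
    geodesic reconstruction, and supports scripted (reproducible) manual
    edits. Companion modules simulate abdominal MRI phantoms with known
    ground truth and synthetic cohorts with a prescribed rank-correlation
    structure, and implement the downstream subject-level statistics:
    HOMA-IR, BMI, partial Spearman correlation with covariates,
    Benjamini-Hochberg false-discovery-rate control and simple linear
    regression summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    Matrix,
    mgcv,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
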