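Package: petseg
Title: Cascaded 2D-3D Convolutional Tumor Segmentation for Whole-Body FDG-PET/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated delineation of metabolically active tumor in eyes-to-thighs
    FDG-PET/CT scans and quantification of metabolic burden (total metabolic tumor
    volume, SUVmax). Implements a cascaded architecture: slice-wise 2D segmentation
    with a dilated separable residual U-Net, deterministic brain/liver/lung landmark
    detection to split the body into head-neck, chest and abdomen-pelvis regions,
    and region-specific 3D V-Net refinement on patches around candidate lesions.
    Includes SUV calibration from DICOM metadata, isotropic resampling, compound
    Dice/cross-entropy and Dice/sensitivity/MAE training losses, desk-scale training
    loops, and a seeded synthetic whole-body phantom generator for fully
    reproducible testing without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
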