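Package: gliomid
Title: Identifiability of Image-Based Models of High-Grade Glioma Response to Chemoradiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Virtual-cohort identifiability analysis for a family of eleven
    image-based reaction-diffusion models of high-grade glioma growth and
    response to fractionated radiotherapy with concurrent chemotherapy.
    Generates synthetic patients (voxelized brain anatomy, enhancing and
    non-enhancing tumour density fields, enhancement-ratio and dose maps),
    grows ground-truth tumours with mechanically coupled diffusion and
    linear-quadratic treatment response, injects observation noise,
    calibrates every model variant by bounded Levenberg-Marquardt nonlinear
    least squares, selects models by corrected AIC, and scores calibration
    and prediction accuracy with Dice, concordance correlation and total
    tumour cellularity error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
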