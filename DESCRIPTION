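Package: biasnet
Title: Neural Bias Field Correction for 3D Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates and removes the smooth multiplicative intensity
    inhomogeneity (bias) field of T1-weighted brain MRI with a 3D U-Net
    regressor trained in log-field space, followed by optional Gaussian or
    multilevel B-spline smoothing of the predicted field and division-based
    correction. Ships a self-contained compiled network core (convolution,
    instance normalization, transpose-convolution upsampling, Adam), a fixed
    preprocessing chain (resampling, padding, percentile normalization, brain
    masking) with an invertible transform record, a synthetic phantom engine
    that generates paired acquired/corrected/field volumes for desk-scale
    training, and evaluation tools (masked PSNR, intensity profiles,
    Wilcoxon signed-rank comparisons with Bonferroni correction, Cohen's d).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    splines,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
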