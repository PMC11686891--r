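Package: mrfsynth
Title: Synthesis of MR Fingerprinting Maps from Magnitude T1-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthesizing magnetic resonance fingerprinting (MRF)
    information from conventional magnitude-only T1-weighted (MPRAGE) brain
    MRI. Implements a Bloch-simulation forward model for MRF fingerprints,
    dictionary construction over a (T1, T2) grid with temporal SVD
    compression, inner-product dictionary matching to T1/T2/proton-density
    maps, a seven-parallel U-Net image-regression network (one network per
    real or imaginary singular-value channel) with ADAM training and
    checkpointing, NIfTI volume preprocessing (resampling, intensity
    normalization, skull-strip masking), a multi-subject digital brain
    phantom generator for download-free experiments, and regional agreement
    statistics (Lin's concordance correlation coefficient with clustered
    bootstrap confidence intervals, mean differences, coefficients of
    variation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
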