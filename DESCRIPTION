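Package: plaspect
Title: Combined Diffusion-Relaxation MRI Decomposition of Placental Tissue Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing combined T2*-diffusion (multi-echo,
    multi-b-value) placental MRI. Implements the joint T2*-ADC forward signal
    model and its acquisition protocol, voxelwise S0/T2*/ADC mapping by
    bounded nonlinear least squares, an unsupervised spectral-component
    decomposition that learns shared non-negative T2*-ADC spectra with
    per-voxel simplex weights (and projects new scans onto fixed spectra),
    digital placental phantom and cohort simulators with known ground truth,
    and the cohort statistics (ANCOVA adjusting for gestational and maternal
    age, Pearson trends over gestation, Benjamini-Hochberg false discovery
    rate correction) used to compare patient groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
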