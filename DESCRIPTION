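Package: stratseg
Title: Stratified Organ-at-Risk Segmentation with Differentiable
    Architecture Search on 3D Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a stratified framework for
    segmenting radiotherapy organs at risk (OARs) in 3D planning-CT-like
    volumes.  OARs are partitioned into anchor, mid-level, and
    small-and-hard (S&H) difficulty strata; anchor structures are
    segmented first and their predicted probability maps guide the
    mid-level segmentation branch and an S&H heatmap-regression
    detection branch, after which small structures are segmented inside
    cropped volumes of interest.  Every branch backbone is an
    encoder-decoder whose convolution blocks are chosen by a
    differentiable architecture search over 2D, 3D, and pseudo-3D
    kernels of size 3 or 5.  The package ships a synthetic phantom
    generator, segmentation metrics (Dice, Hausdorff, average surface
    distance) computed in physical millimetres, dose-volume histograms,
    and direct and clinical dosimetric difference statistics, so the
    full pipeline is exercisable on a CPU with no clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
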