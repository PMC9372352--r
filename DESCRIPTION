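Package: wmhseg
Title: White Matter Hyperintensity Segmentation with a Lightweight 2D
    Encoder-Decoder Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation and quantification of white matter
    hyperintensities (WMH) on thick-slice multi-modal brain MRI
    (T1-weighted, T2-weighted, FLAIR).  Provides a synthetic phantom
    generator for thick-slice studies with ventricles and lesions,
    quantile intensity normalization and in-plane resampling, two-rater
    label fusion with definite/suspected partitions and distance-based
    loss weight maps, a lightweight fully convolutional 2D encoder-decoder
    network (VB-Net style, with bottleneck and residual blocks) trained
    with a weighted Dice loss, a full voxel- and lesion-level evaluation
    metric suite (Dice, recall, precision, lesion recall, lesion F1,
    average volume difference, 95th-percentile Hausdorff distance),
    ventricle-distance-based WMH subclassification (juxtaventricular,
    periventricular, deep, juxtacortical), and a bootstrap comparison of
    Spearman correlations against ordinal visual rating scores.
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
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
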