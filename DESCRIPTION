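Package: ichseg
Title: Unsupervised Haematoma and Perihaematomal Oedema Segmentation from MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Training-free segmentation of haematoma and perihaematomal oedema
    from co-registered T2* gradient-recalled-echo and FLAIR MR volumes of
    acute and early-subacute spontaneous intracerebral haemorrhage. Haematoma
    is detected as robust intensity outliers (univariate Minimum Covariance
    Determinant location and scale with a chi-squared cutoff) refined by
    connected-component shape and context scoring and a skewness-corrected
    FLAIR threshold; oedema is delineated by a voxel-wise dynamic threshold
    driven by the geodesic quasi-euclidean distance from the haematoma and a
    small-vessel-disease weight map. Includes anatomical mask construction
    from atlas label maps, a seedable synthetic phantom generator for
    validation without patient data, NIfTI input/output, and Dice evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
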