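Package: segda
Title: Source-Relaxed Semi-Supervised Domain Adaptation for 3D Anatomical
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-class 3D anatomical segmentation with an anisotropic
    encoder-decoder network and a two-stage, source-relaxed domain
    adaptation pipeline: decoder-frozen transfer learning on a handful of
    labeled target cases, followed by uncertainty-guided self-learning on
    unlabeled target cases using deep-ensemble pseudo-labels, a masked
    partial Dice loss, and entropy-derived sample weights.  Ships a
    synthetic anisotropic phantom generator with a controllable
    source-to-target domain shift so the whole pipeline can be exercised
    and validated end-to-end on a single CPU, plus NIfTI/NRRD volume I/O,
    the preprocessing recipes (resampling, center cropping, intensity
    normalization, augmentation), connected-component post-processing, and
    Dice / average-boundary-distance evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
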