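Package: seanet
Title: Spiral Attention and Squeeze-and-Excitation Network for Biomedical
    Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encoder-decoder semantic segmentation for class-imbalanced
    biomedical images. Implements the SEA-Net architecture, a U-Net
    derivative in which plain skip connections are replaced by a closed
    spiral path of attention gates and squeeze-and-excitation residual
    blocks, together with its hybrid cross-entropy plus Tversky training
    objective and binary-mask evaluation metrics (Dice, sensitivity,
    specificity, accuracy). Includes a reverse-mode differentiation core
    with C++ convolution kernels, an Adam training loop, synthetic
    generators for brain-slice-like and blood-smear-like fixtures, PNG and
    NIfTI data loaders, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    RNifti,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
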