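Package: lungreg
Title: Three-Stage Deformable Registration of Dynamic Lung Fields in Chest Radiograph Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic three-stage registration of dynamic lung fields in
    chest X-ray (CXR) sequences: lung-field segmentation, pixel-wise lung-field
    extraction, and anatomically constrained deformable registration trained by
    a three-step scheme (initial training on all ordered image pairs, enhanced
    training on affine-augmented pairs, final training on extracted lung-field
    pairs). The registration network predicts a dense displacement field that a
    differentiable warper applies by backward bilinear sampling; training
    minimises a composite loss of negative normalized cross-correlation,
    total-variation smoothness, binary cross-entropy on warped masks, and an
    anatomical latent-space penalty from a pretrained denoising autoencoder.
    Includes a seeded breathing-phantom generator with ground-truth dense
    deformations, registration evaluation metrics (Dice, Hausdorff, average
    symmetric surface distance, mean squared distance) with paired significance
    testing, raster and displacement-field IO, and an ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    jsonlite,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'generics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cli.R'
    'extraction.R'
    'io.R'
    'losses.R'
    'lungreg-package.R'
    'metrics.R'
    'networks.R'
    'nn.R'
    'phantom.R'
    'pipeline.R'
    'study.R'
    'training.R'
    'utils.R'
    'warp.R'
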