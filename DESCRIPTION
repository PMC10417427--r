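Package: csrseg
Title: Coarse-to-Fine Segmentation of Small Lesions in 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and segmentation of small lesions in anisotropic 3D
    grayscale volumes using a coarse-to-fine fusion pipeline: liver and
    coarse lesion segmentation with CSR-UNet networks (squeeze-and-excitation
    residual U-Net blocks, in 3D and 2.5D multi-slice variants), a size-gated
    detection stage producing fixed 64x64x5 regions of interest around
    candidate lesions smaller than 30 mm, fine segmentation of those crops,
    and fusion of the coarse and fine results. Includes a synthetic phantom
    generator (organ plus ellipsoidal lesions with controlled long diameters),
    Focal Tversky loss, sliding-window patch inference with Gaussian
    weighting, online augmentation, and lesion-wise evaluation stratified by
    long diameter (5-10, 10-30, >30 mm) reporting Dice, IOU, volumetric
    similarity, F1 and recall. Networks are trained with a compact built-in
    neural-network engine (BLAS-backed convolutions via Rcpp).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
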