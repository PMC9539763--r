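Package: synthCT
Title: Multi-Planar Conditional-GAN Synthesis of CT from Low-Field MR with
    Dosimetric Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic CT volumes from low-field MR volumes with a
    conditional generative adversarial network trained on 2D planes sampled in
    three orthogonal directions and fused by voxelwise averaging. Includes
    procedural paired pelvis phantoms for fully reproducible experiments,
    MR/CT intensity preprocessing (exterior masking, Hounsfield-unit affine
    normalization, z-score MR normalization, homomorphic bias-field
    correction), the composite adversarial + L1 + normalized-mutual-information
    training objective, image-quality metrics (MAE, ME, PSNR, global SSIM,
    Hounsfield-threshold tissue segments), and dosimetric comparison tools
    (cumulative dose-volume histograms with D95%/D2%, 3D gamma analysis with
    global normalization).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
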