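Package: tausynth
Title: Cross-Modality Tau-PET Synthesis with a 3D Dense-U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputes tau-PET-like volumes from FDG-PET-, amyloid-PET- or
    T1w-like template-space inputs with a 3D Dense-U-Net trained under a
    subject-grouped five-fold protocol. Includes a synthetic phantom cohort
    generator with known cross-region coupling, SUVR and white-matter
    intensity normalization, the deterministic crop/pad between template
    (121x145x121) and network (128x128x128) space, regional-SUVR evaluation
    (Pearson r, MAPE, voxel-wise RMSE maps, MS-SSIM), tau-positivity and
    diagnostic-group ROC analyses, and ROI-occlusion sensitivity matrices.
    The network forward and backward passes and the Adam optimizer are
    implemented in compiled code via GEMM-based 3D convolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
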