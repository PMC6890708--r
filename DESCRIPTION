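Package: voxcae
Title: Volumetric Convolutional Autoencoders for Brain MRI Classification
    and Saliency Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying 3D structural brain volumes
    with small volumetric convolutional neural networks: convolutional
    autoencoder (CAE) and inception-module (ICAE) architectures with
    unsupervised reconstruction pretraining, supervised fine-tuning,
    source-to-target transfer learning for subtle contrasts such as
    progressive versus stable mild cognitive impairment, gradient-based
    class saliency maps, and supervoxel occlusion sensitivity analysis.
    Includes a synthetic brain-phantom generator with planted ground-truth
    lesions so that classification, transfer, and saliency localization
    can be validated without access-restricted clinical data, plus
    nested cross-validation with an inner grid search and a leakage audit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
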