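Package: mciprog
Title: Voxel-Based Morphometry Guided 3D CNN Classification of MCI Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for predicting
    conversion from mild cognitive impairment (MCI) to Alzheimer's disease from
    structural brain MRI. Provides a synthetic cohort generator emulating
    grey-matter probability volumes with focal atrophy, a self-contained
    preprocessing chain (polynomial bias-field correction, Gaussian-mixture
    tissue segmentation, affine normalization to a template grid, FWHM
    Gaussian smoothing), voxel-based morphometry (mass-univariate GLM with
    permutation-based family-wise error control and peak extraction), MNI
    coordinate-guided cubic patch extraction, and two seeded 3D convolutional
    classifiers - a whole-volume network and a region-guided network fusing
    patch embeddings with peak Z-scores - together with subject-level
    splitting, augmentation, training, evaluation, and saliency mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    mclust,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
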