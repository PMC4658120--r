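Package: vbforest
Title: Random-Forest Localization and Segmentation of Vertebral Bodies in 3D CT/MR Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified random-forest regression and classification framework for
    fully automatic localization of vertebral-body centers and voxel-wise
    segmentation of vertebral bodies in 3D CT and MR volumes. Localization uses
    regression forests that cast displacement votes from randomly sampled image
    patches; votes are aggregated into a per-voxel response volume with a
    Gaussian transform (exactly, or via the improved fast Gauss transform), and
    the chain of vertebral-body centers is regularized with a hidden Markov
    model decoded by dynamic programming. Segmentation fuses a Parzen-window
    spatial prior with a classification-forest appearance likelihood inside a
    region of interest around each detected center. Includes 3D integral-image
    block features, NIfTI and MetaImage volume I/O, a synthetic spine phantom
    generator, and the standard evaluation metrics (localization distance,
    detection rate, Dice, average and Hausdorff surface distance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
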