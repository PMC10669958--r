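Package: cbctCaries
Title: Per-Tooth Caries Lesion Localization in CBCT and Reader-Study Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open re-implementation of the per-tooth caries-sign localization
    pipeline used in dental cone-beam computed tomography (CBCT) decision support:
    tooth sub-volume extraction with invertible crop/resample geometry, a 3D
    attention U-Net with deep supervision and a tooth-level classification head
    trainable on CPU, connected-component lesion post-processing with physical
    volume thresholds and Youden-anchored probability recalibration, and the full
    reader-study evaluation machinery (sensitivity/specificity/accuracy, Cohen's,
    weighted and Fleiss kappa, ROC analysis of five-point confidence ratings,
    consensus ground truth with adjudication). A seeded procedural phantom
    generator provides tooth volumes, lesion masks and synthetic observer rating
    tables so the whole pipeline is testable without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'agreement.R'
    'cbctCaries-package.R'
    'extract.R'
    'net-layers.R'
    'net-train.R'
    'net-unet.R'
    'phantom.R'
    'pipeline.R'
    'postprocess.R'
    'ratings.R'
    'resample.R'
    'utils.R'
    'volume-io.R'
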