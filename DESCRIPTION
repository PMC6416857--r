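Package: rcaqc
Title: Reverse Classification Accuracy for Automatic Segmentation Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-case quality control of multi-class anatomical segmentations
    without ground truth using reverse classification accuracy (RCA). A set of
    verified reference atlases is registered to the test image (centre-of-mass
    alignment followed by deformable registration), the reference label maps
    are warped onto the test grid, and the best agreement between any warped
    reference segmentation and the test segmentation - Dice similarity
    coefficient and mean, root-mean-square and Hausdorff surface distances -
    is taken as the predicted quality of the test segmentation. Includes
    good/poor classification at configurable thresholds, confusion statistics,
    prediction-error summaries, a reference-set-size experiment, NIfTI-1
    input/output, and a synthetic short-axis cardiac phantom generator with a
    controlled segmentation-degradation engine for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'rcaqc-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'core-model.R'
    'io.R'
    'metrics.R'
    'phantoms.R'
    'registration.R'
    'rca.R'
    'quality.R'
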