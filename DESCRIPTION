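Package: ntatlas
Title: Normative Tractographic Atlas Construction and Lesion Scoring for
    MRgFUS Thalamotomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds normative tractographic atlases (NTA) from per-subject
    probabilistic seed-to-terminus connectivity maps, fits them to individual
    patients, and scores ablation lesions with the normative tractography
    coefficient (NTC), the mean atlas value over the coregistered lesion.
    Includes a simplified probabilistic streamline tracker over analytic
    orientation fields, affine and displacement-field spatial transforms with
    NIfTI-1 input and output, stereotactic targeting helpers, synthetic
    phantom and cohort generators with known ground truth, and the
    cohort-level outcome statistics (ROC curves with Youden-optimal cutoffs,
    Kruskal-Wallis tests, Fisher exact tests, adverse-event summaries) used
    to relate lesion volume, accumulated dose volume and NTC to quality-of-
    life outcome after focused-ultrasound thalamotomy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
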