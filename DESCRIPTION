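Package: phantomQA
Title: Phantom-Based QA of Auto-Generated Body Contours and Adapted Dose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico phantom study framework for quality assurance of
    automatically generated body contours and adapted dose in online adaptive
    radiotherapy. Generates synthetic neck-like CBCT phantoms with uniform
    surface layers, bolus shells and configurable air gaps; implements a
    Hounsfield-unit homogenization algorithm that converts bolus-plus-airgap
    images into simulated weight-loss images; extracts body contours by
    multi-threshold segmentation with a three-threshold baseline and its
    uncertainty; computes contour volume-deviation statistics (mean absolute
    deviation, thickness-volume linear-fit R squared with population
    variances); and evaluates dose with DVH metrics (D95%, D99%), a 3-D gamma
    index (dose difference / distance-to-agreement), and an analytic
    ray-marching toy dose model contrasting scheduled versus adapted plans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    zoo,
    EBImage,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
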