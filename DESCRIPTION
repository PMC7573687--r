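Package: cecleanr
Title: Objective Cleanliness Scoring of Capsule Endoscopy Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective, reproducible evaluation of small-bowel
    cleanliness in capsule endoscopy video frames. A light-weight
    convolutional neural network classifies overlapping 64x64 image patches
    as clean mucosa or intestinal content; patch probabilities are bilinearly
    interpolated to per-pixel probabilities, and the mean pixel probability
    inside the circular field of view is converted to a four-category
    cleanliness evaluation score (Poor, Fair, Good, Excellent) through
    thresholds learned by maximising single-rater consistency intraclass
    correlation against expert ratings. Includes interrater agreement
    statistics (linearly weighted Cohen's kappa with confidence intervals,
    single-rater ICC in consistency and absolute-agreement forms), grouped
    cross-validation utilities, and a synthetic frame generator so every
    stage can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jpeg,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
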