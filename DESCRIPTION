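Package: fairseg
Title: Fairness-Aware Curriculum and Federated Training for Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying demographic fairness in semantic segmentation of
    medical images. Provides curriculum schedulers (self-paced, teacher-student,
    and balanced growing-subset curricula with demographic interleaving),
    progressive loss functions that sweep emphasis from easy to hard samples,
    subgroup fairness metrics (per-sample IoU, group-level SD, skewed error
    ratio, min-max disparity, paired t-tests), and a simulator for federated
    training across non-IID sites with six aggregation rules including
    differential-privacy noise, inverse-SER and IoU-based client weighting, and
    interquartile-range outlier pruning. A compact U-Net backbone and a
    synthetic radiograph-like data generator with controllable group-dependent
    difficulty allow the full pipeline to run end-to-end on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
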