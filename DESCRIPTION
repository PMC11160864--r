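Package: hlfd
Title: Hierarchical Layer-Selective Feedback Distillation for Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Knowledge distillation for compact medical image segmentation
    networks. Implements hierarchical layer-selective feedback distillation:
    attention-transfer feature losses from a teacher's unified middle layers
    to the student's early layers and from the teacher's terminal layer to
    each student middle layer, plus pixel-level Kullback-Leibler distillation
    of teacher decoder predictive maps against interpolated student maps,
    combined with a supervised focal-dice segmentation loss in a multi-task
    objective. Ships miniature reference teacher and student networks with a
    built-in reverse-mode differentiation engine, a synthetic CT phantom
    generator with Hounsfield-unit windowing, Adam training with cosine
    annealing, and Dice / relative-volume-difference evaluation, so the whole
    pipeline runs and is testable on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
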