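Package: ecodistill
Title: Knowledge Distillation for Lightweight Speech Detection in Eco-Acoustic Audio
Version: 0.1.0
Authors@R:
    person("Eco", "Distill", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating compact voice activity detectors for
    passive acoustic monitoring. Generates synthetic eco-acoustic audio pools
    (speech-like, environmental background, bird-like, and ambient soundscapes),
    assembles balanced labelled datasets of 3-second clips by SNR-controlled mixing,
    converts clips to normalized 128x128 log-Mel spectrograms, and trains a VGG11
    (batch-normalized) teacher alongside four MobileNetV3-Small-Pi style student
    networks with soft-target, feature-based (hint/guide), and relational knowledge
    distillation. Includes an efficiency profiler (parameters, multiply-accumulate
    operations, memory) and a statistical evaluation harness (F1, AUC, bootstrap
    confidence intervals of medians, Mann-Whitney U comparisons, distance-stratified
    playback reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    matrixStats,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
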