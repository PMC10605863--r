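Package: beatcam
Title: Beat-Level ECG Classification of Paediatric BMI Status with 1D
    Grad-CAM++ Explanations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for detecting obesity-associated changes in
    single-lead paediatric electrocardiograms. Provides a synthetic cohort
    generator (sum-of-Gaussians PQRST morphology with configurable
    class-dependent differences, heart-rate variability and noise), XML
    record ingestion and validation, FIR band-pass filtering, Hamilton-style
    R-peak detection, complete-beat extraction, BMI categorisation with
    sex-specific cutoffs, subject- or beat-level dataset splitting, a fully
    specified 1D convolutional neural network classifier trained with Adam
    and early stopping, Grad-CAM++ relevance maps adapted to 1D signals with
    class-level aggregation and overlap profiles, a compact neural
    architecture search harness (random and genetic strategies), and report
    generation (mean-beat profiles, confusion matrices, relevance figures).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Rcpp,
    xml2,
    signal,
    jsonlite,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
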