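Package: nodulecam
Title: Lightweight 3D Convolutional Networks with Grad-CAM Explanations for
    Lung Nodule Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for binary lung-nodule classification on volumetric CT
    crops with a lightweight 3D convolutional neural network and
    gradient-weighted class activation mapping (Grad-CAM) for visual
    explanation of model decisions. Provides declarative architecture
    descriptions with a closed-form parameter-count audit, a compact
    volumetric conv-net engine (forward, backward, Adam training) written in
    C++, a synthetic nodule-phantom generator with ground-truth masks so the
    whole pipeline runs at desk scale without patient data, confusion-matrix
    and ROC/AUC evaluation, NIfTI/NRRD volume input/output, and a
    command-line interface covering data generation, architecture audit,
    training, evaluation, and Grad-CAM explanation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
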