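Package: readernet
Title: Reader-Embedding Convolutional Classification for Multi-Annotator
    Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for training and evaluating convolutional classifiers of
    paediatric chest radiographs annotated by a panel of readers under a
    WHO-style five-category scheme. Implements a reader-embedding classifier
    whose image embedding is modulated element-wise by a learned per-reader
    embedding, trained on individual reader labels and evaluated by
    unweighted-mean aggregation of per-reader predictions, alongside the
    conventional final-label baseline. Includes a multi-reader annotation and
    arbitration simulator with per-reader confusion matrices and age-dependent
    agreement, patient-level data splitting, per-reader epoch sampling,
    learning-rate schedules and per-group optimisation, one-vs-rest AUC and
    confusion-matrix evaluation, Grad-CAM saliency maps, and synchronous
    successive-halving hyper-parameter search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
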