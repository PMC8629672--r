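Package: fwnnet
Title: Fuzzy Wavelet Neural Networks for Image Classification and Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements an eight-layer fuzzy wavelet neural network (FWNN):
    Takagi-Sugeno-Kang fuzzy rules with Gaussian antecedents whose consequents
    are wavelet-network outputs, trained by a hybrid scheme of particle swarm
    optimization (plain or blockwise "inline" variant) followed by gradient
    descent with analytically derived gradients. Includes a histogram feature
    extractor that models 8-bit image intensity histograms as a sum of four
    Gaussian modes, an eigen-decomposition image reduction, a patch-based
    supervised tumor-segmentation mode built on a Gabor filter bank, an
    evaluation harness (confusion matrices, sensitivity, precision, ROC/AUC,
    standard baseline classifiers), and a synthetic MRI-like phantom generator
    so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    png,
    jsonlite,
    yaml,
    EBImage,
    MASS,
    class,
    e1071,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
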