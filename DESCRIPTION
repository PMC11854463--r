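Package: daqugrade
Title: Two-Layer Machine-Vision Grading of Daqu Fermentation Starter Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for grading light-flavor Daqu (the pressed barley-and-pea
    fermentation starter used in Chinese Baijiu brewing) from cross-section
    images. Provides a seeded synthetic image generator emulating the
    grade-dependent visual structure of Daqu blocks (grayish-blue premium
    centers, red spots of first grade, cracks and dark rims of second grade);
    three block-segmentation back-ends (Otsu thresholding, seeded k-means
    color clustering, and a morphological fusion of Canny edges with dilation,
    hole filling and small-object removal); center/Pizhang region-of-interest
    partitioning; 14- and 38-factor color and pixel feature extraction with
    4-bin RGB histograms; four feature-selection methods (random-forest
    permutation importance, recursive feature elimination, LASSO and ridge
    regression with a cross-validated lambda grid); SVM, random forest,
    logistic regression, k-nearest-neighbor and stacked ensemble classifiers
    arranged in a two-layer grade decision; and an evaluation toolkit with
    stratified splits, cross-validation, confusion-matrix metrics, ROC/AUC and
    PCA decision-boundary plots.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    png,
    EBImage,
    ranger,
    glmnet,
    e1071,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
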