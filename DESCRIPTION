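Package: mblstm
Title: Predicting Host Phenotype from Longitudinal Microbiome Profiles
    with LSTM Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a binary host phenotype (food allergy) from
    variable-length longitudinal gut-microbiome taxonomic profiles. Provides
    cohort assembly from genus-level abundance and sample-metadata tables,
    a Dirichlet-multinomial synthetic-cohort generator with a planted
    class-dependent temporal signal, three feature representations
    (minimum-redundancy-maximum-relevance selection, variance ranking, and a
    sparse autoencoder with a KL-divergence sparsity penalty), an LSTM
    sequence classifier with last-timepoint readout, five baseline
    classifiers (HMM with Gaussian-mixture emissions, multi-layer
    perceptron, random forest, SVM, LASSO), and a repeated cross-validation
    benchmark reporting sensitivity, specificity, auROC and the Matthews
    correlation coefficient with Mann-Whitney comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    glmnet,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
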