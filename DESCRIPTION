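Package: swtcnn
Title: Prognostic Risk Stratification from Expression Profiles with
    Stationary Wavelet Transforms and a Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies cancer patients into prognostic risk groups from bulk
    gene-expression profiles. Each sample's profile is decomposed with a
    stationary (undecimated) wavelet transform, the stacked approximation
    coefficients are classified by a one-convolutional-layer neural network,
    and the network's post-pooling representative features are mapped back to
    per-gene importance scores by minimum-norm least squares. Top-scoring
    genes feed univariate and multivariate Cox proportional-hazards models
    whose linear predictor, thresholded at a ROC-derived cutoff, assigns
    high/low risk groups evaluated by Kaplan-Meier and log-rank analysis.
    Includes SVM, random-forest and logistic-regression baselines, a
    repeated random-split benchmarking protocol, and a synthetic cohort
    simulator with proportional-hazards survival and right censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    MASS,
    survival,
    glmnet,
    e1071,
    randomForest,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
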