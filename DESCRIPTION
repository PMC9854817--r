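Package: ramandx
Title: Serum Raman Spectral Preprocessing and Diagnostic Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for classifying serum Raman spectra into diagnostic
    groups (healthy control, breast cancer, ductal carcinoma in situ).
    Provides a synthetic spectrum generator with Lorentzian peak profiles
    and a fluorescence-like polynomial background, spectral preprocessing
    (Savitzky-Golay smoothing, adaptive iteratively reweighted penalized
    least squares (airPLS) baseline correction, min-max scaling), four
    classifier families (a one-dimensional convolutional neural network
    trained with Adam, k-nearest neighbours, random forest, and an RBF
    support vector machine with one-vs-rest decomposition) with stratified
    5-fold cross-validated grid search, and a full evaluation protocol:
    stratified 7:3 train/test split, three-class and pairwise binary
    experiments, confusion matrices, sensitivity/specificity and
    one-vs-rest macro-averaged ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    class,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
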