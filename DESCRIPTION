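Package: svmFSS
Title: Counter-Voting SVM Ensembles on Feature Subspaces for Imbalanced
    Multiclass Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ensemble classification of imbalanced multiclass gene-expression
    data. Multiclass problems are decomposed one-against-all; for each binary
    branch a feature space of K genes is built by hierarchical clustering on
    Pearson correlation followed by per-cluster signal-to-noise-ratio
    selection, and L base RBF-kernel support vector machines are trained on
    random D-gene feature subspaces. Class imbalance inside each training
    subset is corrected either by decision-threshold adjustment or by random
    undersampling, and predictions are decoded by counter voting. Includes
    imbalance-aware multiclass metrics (G-mean, F-score, weighted accuracy),
    a repeated stratified cross-validation protocol with per-branch RBF grid
    search, a subspace-dimension sensitivity sweep, and a synthetic-data
    generator with planted informative, redundant and noise genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
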