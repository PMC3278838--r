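Package: amyhex
Title: Amyloidogenic Hexapeptide Prediction from Heterogeneous Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether six-residue peptide windows (hexmers) are
    amyloidogenic, i.e. prone to assemble into amyloid-like fibrils.
    Hexmers cut from protein sequences by a sliding window are encoded as
    heterogeneous feature vectors: per-window means of amino-acid property
    indices (bio-physio-chemical block), Moreau-Broto autocorrelation of
    selected indices at lags 1-5 (sequence-order block), and C/H/N/O/S
    atomic composition. A two-stage feature-optimization engine -- embedded
    linear-SVM pre-selection followed by a memetic algorithm whose fitness
    is 5-fold cross-validated RBF-SVM accuracy, with F-score-ranked
    Add/Delete local search -- picks a fixed-size property subset. Five
    feed-forward neural-network prediction-model configurations are trained
    on the resulting feature blocks and evaluated with sensitivity,
    specificity, balanced accuracy, Matthews correlation, ROC/AUC and
    ROC-space quadrant analysis. Synthetic generators for labeled hexmer
    sets, amino-acid indices, and planted-signal feature matrices make the
    whole pipeline testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
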