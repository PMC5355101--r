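Package: psepred
Title: Pseudo-Component Sequence Classification with RBF-SVMs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary sequence classifiers for DNA, RNA and protein from a
    positive/negative FASTA benchmark. Sequences are encoded as pseudo k-tuple
    nucleotide composition (PseKNC) or pseudo amino acid composition (PseAAC)
    vectors: a k-mer composition block plus lambda pseudo components derived
    from physicochemical property correlations along the sequence. Feature
    hyperparameters (k, lambda, w, correlation mode) and RBF-SVM parameters
    (C, gamma) are selected jointly by cross-validated grid search, with
    stratified K-fold and jackknife engines, pooled Acc/MCC/Sn/Sp/AUC metrics
    and tie-aware ROC curves. Fitted models are persisted as versioned text
    archives and applied to query sequences; a seeded synthetic benchmark
    generator with planted motif or compositional signal supports end-to-end
    testing.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    jsonlite,
    parallel,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    pROC,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
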