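Package: combind
Title: Random Forest Models for Transcription Factor Pair Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint transcription-factor-pair (TF-TF) binding site prediction
    from short SELEX-style DNA reads with two random forest models: JointRF,
    which trains a forest on sub-sequences selected with a pairwise
    (composite) position weight matrix, and ComBind, which trains one forest
    per binding orientation on 25-nt windows selected with uniformly extended
    individual-TF matrices and averages the two orientation scores. Includes
    dinucleotide-count-preserving shuffling for negative-set construction
    (random Euler path method), PWM parsing/scanning with N-padding and
    double-strand maximum-per-position scoring, class-balanced data splitting
    with pre-training hyperparameter grid search, AUROC and Wilcoxon
    signed-rank model comparison, a synthetic dimer-motif read simulator for
    benchmarking, and motif construction from forest out-of-bag predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
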