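Package: fexsplice
Title: Predicting the Splicing Effect of Variants at the First Nucleotide of an Exon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a single-nucleotide variant at the first
    (reference G) nucleotide of an internal exon disrupts pre-mRNA splicing.
    Extracts 115 splicing cis-element features around the acceptor site
    (branch point sequence, polypyrimidine tract, positional nucleotides,
    Shapiro-Senapathy / maximum-entropy / SD splice-site strength scores,
    and RNA-binding-protein motif sum scores), trains gradient-boosted,
    linear-SVM and random-forest classifiers with grid search, performs
    cross-validated evaluation (seven confusion-matrix statistics, AUROC,
    AUPRC) and importance-guided recursive feature elimination, and
    classifies variants at a 0.5 probability threshold. Includes a seeded
    synthetic acceptor-context generator emulating the AG-dependence of
    3' splice sites so the whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    xgboost,
    randomForest,
    e1071,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
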