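Package: mirsig
Title: MiRNA Signature Discovery for Two-Class Tumor Staging via an
    Inheritable Bi-Objective Combinatorial Genetic Algorithm and RBF-SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for binary tumor-stage classification
    from expression matrices (bulk miRNA-seq or similar). An inheritable
    bi-objective combinatorial genetic algorithm (IBCGA) with orthogonal-array
    crossover searches feature subsets of increasing size r while an RBF-kernel
    support vector machine scores each subset by pooled k-fold cross-validation
    accuracy. Multi-run consolidation via appearance scores yields a robust
    signature, whose members are prioritized by main-effect-difference (MED)
    analysis on an orthogonal include/exclude design. Includes classification
    metrics (sensitivity, specificity, MCC, accuracy, AUC), Hanley-McNeil
    standard errors and two-AUC comparison, Pearson co-expression screening,
    Spearman clinical correlation, and a synthetic-data generator with planted
    informative features for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
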