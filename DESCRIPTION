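Package: oplshda
Title: Orthogonal Partial Least Squares Hierarchical Discriminant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven multiclass classification for omics data by
    hierarchical discriminant analysis built on two-class OPLS-DA models
    (OPLS-HDA). All pairwise one-vs-one OPLS-DA models are fitted with
    stratified k-fold cross-validation, their cross-validated predictions are
    converted into Cohen's d class separability distances, the classes are
    clustered agglomeratively, and the resulting dendrogram is populated with
    two-class OPLS-DA decision models to form a top-down decision tree. New
    samples are classified by traversing the tree. Includes cross-validated
    score tables with Hotelling's T-squared confidence ellipses, volcano
    statistics per split, Newick export of the class dendrogram, seeded
    synthetic data generators with known class geometry, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
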