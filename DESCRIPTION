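Package: microshap
Title: Local Shapley Explanations for Cross-Study Microbiome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Case-control analysis of gut microbiome relative-abundance tables
    with per-sample Shapley (SHAP) feature attributions. Provides abundance and
    prevalence filtering, leave-one-dataset-out (LODO) random-forest
    classification across studies, an exact interventional Shapley engine for
    tree ensembles (brute-force subset enumeration plus a fast tree-walk
    algorithm in C++), PCA embedding of the attribution matrix, K-means
    subtyping of case subjects with elbow-based cluster-count selection,
    per-cluster taxon enrichment tests (Kruskal-Wallis, Mann-Whitney), a seeded
    multi-study synthetic cohort generator, and waterfall/summary report
    builders with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    ggplot2,
    optparse
Config/testthat/edition: 3
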