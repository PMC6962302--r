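Package: placmine
Title: Integrative Mining of Placental Methylome and Transcriptome in
    Fetal Growth Restriction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for case-control integration of placental
    DNA methylation and gene expression microarray data in intrauterine
    growth restriction (IUGR) studies. Provides per-feature differential
    screening with a Levene variance-homogeneity gate, pooled Student
    t-tests and Benjamini-Hochberg false discovery rate control;
    cross-omics gene overlap and methylation-expression correlation;
    literature mining of significant genes via tf-idf, latent semantic
    analysis and k-means clustering of per-gene abstract corpora; and
    prediction of IUGR sub-phenotypes (case-control status, premature
    birth, birth weight and head circumference Z-scores) with SMOTE
    oversampling, grid-search cross-validated support vector machines,
    permutation feature importance and export of a feature-trait
    importance network. A synthetic-data generator with known planted
    structure makes every stage testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
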