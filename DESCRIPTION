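Package: keystoneExpr
Title: Category-Level Expression Analysis of Developmental Keystone Genes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies developmental genes by the phenotypic severity of
    their null mutations (progression, shape, tissue, dispensable, double)
    and quantifies category-level expression patterns in bulk and
    single-cell RNA-seq count data. Implements gene-set resampling tests
    with one-tailed Monte Carlo p-values, single-cell quality-control
    filtering, median-of-ratios size-factor normalization, pseudobulk
    aggregation, per-cell transcript-abundance statistics, and the
    decomposition of organ-level expression into expression-domain size
    and cell-level abundance. Includes a negative-binomial synthetic-data
    generator that reproduces the statistical structure the analysis
    assumes, so the full pipeline runs and is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    matrixStats,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    withr,
    jsonlite,
    yaml,
    digest
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
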