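Package: scwaterfall
Title: Genotype-Contrasted Single-Cell Analysis of the Monocyte-to-Macrophage Waterfall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for droplet single-cell RNA-seq contrasts of
    monocyte-to-macrophage differentiation between two genotypes (control vs
    conditional knockout). Covers 10x-style UMI matrix input, cell and gene
    quality control with fixed bimodality-derived thresholds, pool-based
    deconvolution normalization, mean-variance decomposition with denoised
    PCA, Ward clustering with a dynamic tree cut, pseudo-bulk Fisher-exact
    reference annotation, self-organizing-map/minimal-spanning-tree condition
    enrichment, differential 2D kernel-density maps, cluster-stratified
    pseudo-bulk negative-binomial differential expression with TMM
    normalization, a competitive gene-set test with a variance inflation
    factor, input-ratio normalization for competitive adoptive transfers, and
    a synthetic-data generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    yaml,
    fgsea,
    scran,
    mclust,
    Rtsne,
    irlba
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
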