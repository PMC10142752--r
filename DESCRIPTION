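Package: gliamux
Title: Multiplexed Immunohistochemistry Phenotyping of Microglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell phenotyping of microglia from multiplexed
    fluorescence immunohistochemistry. Provides mask-based cell
    identification from multi-channel tissue images, per-cell quantification
    of five microglial functional markers (L-ferritin, HLA-DR, CD68, CD74,
    Iba1), tissue-wide pathology-load measures for pTDP-43 and GFAP,
    high/low marker gating with valley or quantile thresholds, t-SNE
    embedding with kNN-Louvain cluster phenotyping, group comparisons under
    two-stage Benjamini-Krieger-Yekutieli false-discovery-rate control,
    Spearman correlation matrices, and a two-way ANOVA arm for longitudinal
    mouse-model designs. A ground-truthed simulator of multi-channel tissue
    images and single-cell tables makes every stage of the pipeline
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    FNN,
    igraph,
    Rtsne,
    car,
    emmeans,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
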