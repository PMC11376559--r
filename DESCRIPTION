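Package: MVST
Title: Multi-View Graph Convolutional Spatial-Domain Detection for Spatial Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised identification of spatial domains in spot-based
    spatial transcriptomics (10X Visium). MVST builds three spot-similarity
    graphs -- spatial proximity, gene-expression similarity and
    histology-image similarity -- learns a per-view embedding with an
    attention-augmented multi-view graph convolutional autoencoder, fuses
    the views into a consistent clustering embedding, and assigns
    spatial-domain labels by deep embedded clustering with a Student-t
    soft assignment. Includes a Space Ranger directory reader, a
    QC/normalisation/HVG/PCA preprocessing pipeline, gray-level
    co-occurrence texture features for histology patches, a synthetic
    Visium-like section simulator with planted domains, dropout and
    Poisson-noise corruption operators, and the adjusted Rand index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    png,
    EBImage,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
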