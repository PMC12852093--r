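Package: taxembed
Title: Taxonomy-Guided Metric Learning for Seedling Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Siamese metric learning for few-shot classification of plant
    seedling images. The core is a taxonomic triplet loss whose per-triplet
    margin is a min-max normalized difference of taxonomic tree distances, so
    that the learned embedding space mirrors a known species taxonomy.
    Also implements the standard triplet loss, a hierarchical triplet loss
    with a periodically rebuilt class hierarchy, a compact trainable
    convolutional encoder, k-shot train/validation/test splitting,
    nearest-embedding classification, and embedding-space evaluation
    (macro precision/recall/F1, Silhouette scores of t-SNE projections,
    exact rank-sum replicate comparisons), plus a generator of synthetic
    tree-structured image datasets for fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    cluster,
    EBImage,
    jsonlite,
    optparse,
    png,
    Rtsne,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
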