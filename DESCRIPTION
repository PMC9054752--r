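Package: nnod
Title: Large-Scale Decoding of Cognitive Concepts from Statistical Brain Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for multi-label decoding of cognitive
    concepts from repository-style collections of fMRI statistical maps.
    Uncurated brain volumes are quality-controlled, standardized to a common
    grid, and projected onto non-negative sparse spatial component
    dictionaries by ordinary least squares; concept labels are extracted from
    free-text annotations against a cognitive ontology and enriched by
    hypernym closure; shallow neural networks over dictionary loadings
    (NNoD) with elastic-net and dropout regularization are trained to score
    all concepts jointly; performance is assessed with label-macro-averaged
    ROC AUC and weighted recall at k under leave-collections-out validation.
    A synthetic-repository generator with known ground truth emulates the
    heterogeneity of public repositories (per-collection baselines, mixed
    map types, noisy annotations, contaminant maps) so every stage is
    testable against truth. Includes gradient-based decoding sensitivity
    maps and encoding maps back-projected to voxel space, and a minimal
    NIfTI-1 reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
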