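Package: cancerCNN
Title: Shallow Convolutional Neural Networks for Cancer Type Prediction
    from Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies tumor and normal samples into cancer types from
    unstructured gene-expression vectors using three shallow convolutional
    neural network topologies (1D-CNN with non-overlapping kernels,
    2D-Vanilla-CNN on a reshaped expression grid, and 2D-Hybrid-CNN with
    orthogonal row/column kernels), together with the log2(FPKM+1)
    preprocessing pipeline, a stratified training and cross-validation
    protocol with early stopping, additive Gaussian noise-robustness
    evaluation, and guided-saliency interpretation that scores genes per
    class and selects candidate marker genes, with differential-expression
    concordance and gene-set enrichment checks. A class-conditional
    simulator of pan-cancer expression with planted tissue-of-origin and
    cancer-specific signatures makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    fgsea,
    pheatmap,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
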