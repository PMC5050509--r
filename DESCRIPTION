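Package: wlmgs
Title: Gene Subset Selection by Weight Local Modularity of Sample Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Filter feature selection for gene expression data. Candidate
    gene subsets are scored by the weight local modularity of a weighted
    k-nearest-neighbour sample graph built in the subset's gene space, and
    a sequential forward greedy search grows the subset until the score
    gain falls below a threshold. Includes the local modularity family of
    scores (LM, WLM and the simplified WLM^s objective), per-gene z-score
    normalization, a stratified cross-validation harness with 1-NN and
    RBF-SVM accuracy estimation and frequency-consensus subsets, and a
    synthetic expression-data generator with known ground truth for
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    optparse
Config/testthat/edition: 3
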