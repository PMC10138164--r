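Package: dynetalign
Title: Pairwise Global Alignment of Dynamic Networks via Temporal Node
    Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pairwise global alignment of dynamic (snapshot-based temporal)
    networks. Nodes are embedded snapshot-by-snapshot with a Skip-Gram model
    whose training state is carried from one time point to the next, so the
    final vectors reflect both topology and its evolution; a cross-network
    cosine-similarity matrix is then resolved into an injective node mapping
    by iterative global score maximization. Includes a Barabasi-Albert-based
    synthetic benchmark generator with parameterized evolution and pair
    divergence, noise-injection protocols, and evaluation utilities (node
    correctness, confusion counts over the candidate Cartesian product,
    ROC/AUC, moving averages) together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
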