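Package: seqtopo
Title: Graph Theory-Derived Alignment-Free Sequence Descriptors and
    Twilight-Zone Homology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes alignment-free descriptors of DNA, RNA and protein
    sequences from artificial 2D graphical representations: pseudo-folded
    2D-Cartesian lattice walks, four-color spiral maps and star graphs,
    with Estrada spectral moments of vertex and edge adjacency matrices,
    Markov-chain stochastic spectral moments and entropies, classical
    topological indices (Wiener, Harary, Randic, Balaban, Kier-Hall,
    Moreau-Broto), sequence autocorrelation vectors and word/information
    theoretic measures. Includes a built-in affine-gap global/local
    alignment engine for all-vs-all identity, similarity and bit-score
    matrices with twilight-zone classification, a remote-homology layer
    combining alignment-based and alignment-free scores, and a seeded
    generator of synthetic homologous families at controlled identity
    bands for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    rpart,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
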