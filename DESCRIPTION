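Package: caembed
Title: Community-Aware Attributed Network Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns low-dimensional node embeddings of undirected,
    unweighted attributed graphs by coupling a neighborhood-enhancement
    autoencoder with a community-aware skip-gram branch trained on random
    walks with negative sampling. Community structure is detected by label
    propagation or two-phase modularity (multilevel) optimization, or
    supplied from an external file, and is blended with node attributes
    and the adjacency matrix into a reconstructed adjacency that the
    autoencoder compresses. Includes the standard evaluation protocols
    (repeated-split node classification with Micro/Macro-F1, and
    connectivity-preserving link prediction scored by cosine-ranked AUC)
    and a planted-partition generator with community-correlated binary
    attributes for fully synthetic end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    e1071,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
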