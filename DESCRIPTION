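Package: cosie
Title: Common Invariant Subspace Models for Collections of Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a sample of networks on a shared, aligned vertex set as
    common subspace independent-edge (COSIE) random graphs: every graph has
    expected adjacency matrix V R V' for a common orthonormal basis V of an
    invariant subspace, with a graph-specific symmetric score matrix R.
    Provides the multiple adjacency spectral embedding (MASE) estimator,
    which concatenates per-graph adjacency spectral embeddings and extracts
    the joint subspace by singular value decomposition, together with
    samplers for COSIE, multilayer stochastic blockmodel and mixed-membership
    blockmodel graphs, profile-likelihood selection of the embedding
    dimension, multilayer spectral community detection, and two-sample tests
    of equality of graph distributions with parametric-bootstrap and
    asymptotic (generalized chi-square) null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    mclust,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
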