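Package: multihub
Title: Connector Hub Mapping in Frequency-Binned Multilayer Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps connector hubs from frequency-binned amplitude-envelope
    functional connectivity using a structurally constrained full multilayer
    network. Source time series are symmetrically orthogonalized, decomposed
    into equal-width frequency bins, and Hilbert amplitude envelopes are
    correlated within and between bins (amplitude-amplitude coupling).
    Connections are normalized against iterative amplitude-adjusted Fourier
    transform (IAAFT) surrogate null distributions, thresholded with
    orthogonal minimum spanning trees, masked by a binary structural
    connectivity matrix, and assembled into a supra-adjacency matrix.
    Hubs are detected by multilayer versatility (a multilayer PageRank) and
    reranked by delta centrality on interconnectedness (DCI), the percent
    drop in interlayer edge count when a node is removed; group-level
    inference uses one-sample sign-flip permutation tests. A synthetic data
    generator with planted cross-frequency coupling and planted connector
    hubs supports end-to-end simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
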