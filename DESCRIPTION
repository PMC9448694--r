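Package: hdedoa
Title: Depth-of-Anesthesia Monitoring from Single-Channel EEG via
    Hierarchical Dispersion Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating depth of anesthesia (DoA) from a
    single-channel electroencephalogram. Implements dispersion entropy and
    its hierarchical extension over a binary average/difference
    decomposition tree, wavelet plus nonlocal-means denoising, sliding
    window segmentation, community-graph feature selection (Louvain
    modularity with Laplacian-centrality influence pruning), least-squares
    support vector machine regression of a 0-100 BIS-like index and
    three-state anesthetic classification, a statistical evaluation suite
    (regression, Pearson correlation, Q-Q comparison, confusion matrices,
    RMSE), and a seeded generator of synthetic anesthetic EEG with
    ground-truth depth trajectories, artifacts and signal-quality dropouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
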