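Package: cpsmerge
Title: Multi-View Clustering by Stability-Guided Merging of Product Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Late-integration multi-view clustering for bulk and single-cell
    transcriptomics. Single-view clustering ensembles, obtained by re-clustering
    noise-perturbed data, are aligned to a reference partition by exact optimal
    transport with Jaccard ground costs. Clusters from two views are crossed into
    Cartesian-product clusters, which are then merged greedily to maximize
    clustering stability (tightness), measured through covering point sets.
    Optional bipartite Leiden super-clustering accelerates merging when the
    product space is large. Per-cluster contributions of each view are
    quantified by tightness-based and matching-weight-based scores. Includes a
    synthetic two-view Gaussian-mixture generator (consensus, complementary,
    mixed and ancillary regimes) and external agreement metrics (ARI, NMI,
    F-measure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix,
    ape
Config/testthat/edition: 3
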