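Package: meristemNet
Title: Network-Based Prediction of Cell Division and Topology Rewiring in the
    Shoot Apical Meristem Epidermis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Represents the epidermal cell layer of the plant shoot apical
    meristem as a cell-connectivity network and models how cell division
    reshapes it. Builds tissue graphs from segmentation exports (cells,
    centroids, surface areas, shared walls), computes a catalogue of per-cell
    topological features under four edge-weighting scenarios (unweighted,
    inverse mean area, inverse shared wall, inverse centroid distance), trains
    class-weighted linear support-vector classifiers for cell-division events
    and for post-division neighbor rewiring (classes 0/1/2), and applies both
    sequentially to propagate a tissue's topology one time step forward, with
    plant-wise cross-validation, permutation controls, learning curves and
    propagation benchmarks. A seeded synthetic tissue simulator (Lloyd-relaxed
    Voronoi tessellations that grow and divide) supplies fully labeled inputs
    so the entire pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    e1071,
    pROC,
    deldir,
    polyclip,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    knitr
biocViews: Network, Classification, CellBiology, GraphAndNetwork, Spatial
Config/testthat/edition: 3
RoxygenNote: 7.3.3
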