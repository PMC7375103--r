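Package: connectoscope
Title: Structural Brain Connectome Construction, Graph Metrics, and
    Group Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds whole-brain structural connectomes from streamline-count
    matrices over a labeled region atlas: voxel-count normalization,
    cohort-referenced proportional thresholding, weak-edge pruning, and
    group averaging. Computes weighted graph measures of integration
    (characteristic path length, global efficiency), segregation
    (Onnela clustering coefficient, multi-iteration consensus Louvain
    modularity), and nodal influence (degree, strength, betweenness
    centrality, participation coefficient), classifies provincial and
    connector hubs, and quantifies module migration and hub
    reorganization between group-level networks. Group inference covers
    split-plot ANOVA for global metrics, label-permutation tests for
    nodal metrics, Spearman clinical correlations, and demographic-table
    comparisons. A synthetic-cohort generator with planted community
    structure, hubs, and group effects provides a ground-truth test
    surface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
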