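Package: annlens
Title: Network Topology, Information Content and Activity Geometry of
    Feed-Forward Classifiers Across Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to track how a small feed-forward image classifier
    reorganises while it learns: signed weighted modularity with Louvain
    maximisation and consensus clustering, cartographic node profiling
    (participation coefficient and module-degree z-score), discrete
    mutual-information maps over input pixels and hidden nodes,
    principal-component analyses of node activity including category
    untangling distances, and permutation-based inference. Includes a
    synthetic glyph-image generator with known class-discriminative
    pixel structure, IDX-format readers and writers so MNIST-style
    datasets can be substituted, and an end-to-end pipeline that trains
    a network, snapshots weights and activities on a logarithmically
    thinned epoch schedule, and runs the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    igraph,
    optparse
Config/testthat/edition: 3
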