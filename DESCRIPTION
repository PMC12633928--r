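Package: fosnet
Title: Regional, Molecular, and Network Analysis of Activity-Tagged Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyzes whole-brain maps of activity-tagged (c-Fos/TRAP)
    neurons that have been segmented and registered to a common coordinate
    framework. Assigns each neuron an atlas region from an annotation
    volume and structure tree, computes regional and cortical-layer
    composition statistics across experimental conditions, infers
    molecular identities by region-constrained nearest-neighbor matching
    against a spatial transcriptomic reference, builds a directed
    weighted "active connectivity" network from a structural
    connection-density matrix and per-region active-neuron counts, and
    characterizes that network with resolution-tunable directed
    modularity and weighted betweenness-centrality hub ranking. Includes
    a synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
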