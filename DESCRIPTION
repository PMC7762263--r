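Package: iacd
Title: Community Detection in Complex Networks by Internode Attraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parameter-free detection of non-overlapping communities in
    undirected, unweighted networks. Node importance is scored as the
    product of degree and k-core index, pairwise attraction between nodes
    is modelled as a gravity-like quantity over second-order
    neighbourhoods, every node is paired with its strongest attractor, and
    pairs are merged into communities by connected components of the pair
    graph. Includes partition-agreement metrics (normalized mutual
    information, adjusted Rand index, purity), LFR-style and
    planted-partition benchmark generators with ground truth, readers and
    writers for edge-list, GML and community-assignment files, and a
    command-line interface for detect/evaluate/benchmark workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
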