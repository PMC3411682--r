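Package: netcascade
Title: Perturbation and Co-Extinction Cascade Analysis for Undirected Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates single, clustered, sequential and random perturbations
    (node or edge removals) on simple undirected networks and quantifies their
    consequences: secondary extinctions (nodes that lose every support link),
    fragmentation into connected components, collapse thresholds of
    degree-ranked attack cascades, and co-extinction curves tracing global
    topology as a function of the fraction of nodes removed. Includes an
    edge-list parser with loop and duplicate handling, global topology
    indicators (density, average degree, average path length), four per-node
    centrality measures (degree, betweenness, closeness with a
    disconnected-graph substitution rule, eigenvector), deterministic synthetic
    network generators for testing (star, path, complete, Erdos-Renyi,
    Barabasi-Albert, bipartite web, bridged modules), component-colored network
    rendering, GraphML export, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
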