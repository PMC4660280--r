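Package: netCrosstalk
Title: Cross-Talk Target Prioritisation in Protein Interaction Networks
    by Differential Betweenness Centrality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies candidate cross-talk proteins between two cellular
    processes from protein-protein interaction data. Parses PSI-MI TAB
    (MITAB) interaction tables, curates them to a single taxon and to
    experimentally supported records, extracts process sub-networks by
    all-shortest-path sampling over curated seed lists, forms the union
    network, and ranks nodes by the differential betweenness centrality
    statistic (delta BC): a node's betweenness in the union network minus
    its betweenness in each process sub-network. High delta-BC nodes broker
    shortest paths that only exist when the two processes are combined and
    are nominated as cross-talk targets. Includes a planted-bridge
    synthetic-interactome generator for benchmarking recovery of known
    bridge nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
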