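Package: clcspread
Title: Near-Optimal Sets of Epidemic Spreaders via Combinatorial Local
    Centrality
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Selects near-optimal seed sets of epidemic spreaders in
    undirected contact networks. Extends local centrality to sets of nodes
    (combinatorial local centrality), provides a plain and a lazy greedy
    maximizer that share the (1 - 1/e) approximation guarantee, a
    discrete-time SIR variant in which each infected node contacts one
    uniformly random neighbour per step, top-k selection by seven standard
    centrality measures for comparison, synthetic graph and max-k-cover
    instance generators (including the directed hardness embedding), and a
    desk-scale experiment harness with reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
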