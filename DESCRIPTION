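Package: rnadual
Title: Dual Graph Representation and Motif Classification of Nucleic Acid Secondary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grains RNA and DNA secondary structures (including
    pseudoknots and multi-chain complexes) into dual multigraphs in which
    helical stems are vertices and single-stranded connectors are edges.
    Provides readers and writers for dot-bracket, CT, BPSEQ and a tabular
    multi-chain complex format; exhaustive enumeration of the dual-graph
    catalog for small vertex counts with identifiers assigned by ascending
    Laplacian-spectrum order; multigraph isomorphism matching via a canonical
    certificate; pseudoknot labelling of catalog graphs through
    realization-word search; grouping of interacting subchains into
    independently folded substructures with a polymer filter and a round-2
    filter refinement; partitioning of dual graphs into pseudoknot- and
    junction-preserving blocks with merged-block subgraph inventories; and
    census, group-classification and log-linear growth reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
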