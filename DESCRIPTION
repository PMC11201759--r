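Package: degnet
Title: Network-Based Prioritization of Differentially Expressed Genes
    Across Subcellular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines differential-expression results with gene-ontology
    cellular-component memberships and protein-protein interaction networks
    to prioritize genes within subcellular structures. Provides
    overrepresentation analysis (Fisher exact test with Benjamini-Hochberg
    correction), term selection with a deepest-child rule, six per-node
    graph metrics on STRING-style interaction networks, a multiplicative
    topological gene weight with explicit zero-substitution rules,
    per-structure fold-change and weight aggregation, cross-structure gene
    sharing tables, and top-fraction key-gene rankings. A synthetic-data
    module generates DEG tables, annotations, and networks with planted
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
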