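Package: xenoKG
Title: Typed Knowledge Graphs for Carcinogen Metabolism and DNA-Adduct
    Pathways
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A validated, scriptable knowledge-graph engine for xenobiotic
    carcinogen metabolism. Provides a typed property-graph schema for
    carcinogen, enzyme, metabolite, DNA-adduct and pathway entities with six
    directed relationship types; a packaged, deterministically built
    reference graph covering nine carcinogen classes (96 nodes, 102 edges);
    carcinogen-class subgraph extraction, node/edge-type filtering and
    substring metadata search with neighbour expansion; topology-aware
    pharmacogenomic gene impact scoring and class-level
    activation/detoxification reservoirs; and readers/writers for a
    canonical JSON dialect, GraphML, Cytoscape JSON, CSV tables and layout
    JSON. A seeded random-fixture generator supports property-based
    testing, and a command-line entry point wires the modules together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
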