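Package: epcr
Title: Protein Structure Comparison by Independent-Set Enumeration over
    Secondary-Structure-Element Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Compares protein tertiary structures through a mixed-graph model
    of their secondary structure elements (SSEs). Each protein becomes a graph
    whose vertices are helices and strands, whose directed path records
    N-to-C chain order, and whose undirected edges record spatial contacts.
    Pairwise comparison is reduced to enumerating the top-K maximum
    independent sets of an auxiliary conflict graph built from high-scoring
    candidate SSE pairs, supporting both sequential and non-sequential
    alignment. Includes a polynomial-time exact solver for the map-width-2
    embedding case via 2-CNF satisfiability, a CLIQUE-based generator of
    ground-truthed test instances, and synthetic toy-protein generators so
    the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
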