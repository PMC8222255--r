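Package: olcanneal
Title: De Novo Genome Assembly by QUBO Annealing over Overlap Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for posing small de novo genome assembly problems as
    quadratic unconstrained binary optimization (QUBO). Reads or k-mers are
    arranged into a directed overlap-layout-consensus (OLC) graph, the
    Hamiltonian path through that graph is encoded either with vertex-position
    variables or, for acyclic graphs, with per-edge indicator variables, and
    the resulting QUBO/Ising problems are minimized with a quantum-inspired
    annealer (SimCIM), classical simulated annealing, or an exhaustive oracle.
    Includes a synthetic read/sequence simulator, Chimera-topology modelling
    with deterministic clique minor embedding, single-edge-cut graph
    partitioning, decoding and sequence reconstruction, and time-to-solution
    (R99/TTS) benchmarking utilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
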