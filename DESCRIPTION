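Package: funCore
Title: Functional Coreness Scoring and Core-Microbiome Design for
    Microbial Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores taxa within undirected microbe-microbe association
    networks by combining network topology (betweenness over shortest
    paths), functional portfolios (weighted binary functional layers with
    redundancy bonuses), and functional balance (a penalty for bridging
    functionally lopsided pairs) into a single "functional coreness"
    index. Provides modularity-based module detection, randomization-based
    specificity of taxa and modules to sample conditions, tools to design
    candidate functional core microbiomes from top-scoring taxa within a
    module, readers and writers for the plain-text input formats, a seeded
    synthetic community generator with planted ground truth, and
    brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    S4Vectors
Config/testthat/edition: 3
RoxygenNote: 7.3.3
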