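Package: diamondR
Title: Disease Module Detection on Protein Interaction Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of disease modules in protein-protein interaction
    networks by iterative seed expansion with the DIAMOnD (DIseAse MOdule
    Detection) algorithm, which agglomerates, one protein per iteration, the
    candidate whose number of links to the current module is most significant
    under a hypergeometric null.  Includes localization statistics for seed
    sets (largest-connected-component size and significance, local
    modularity), a seed-weighted generalization of the connectivity
    p-value, synthetic planted-module benchmarks with recovery curves,
    network perturbation models (link pruning and degree-preserving
    rewiring), leave-one-seed-out robustness analysis, a random-walk-with-
    restart baseline, and annotation-based (GMT gene set) validation of the
    ranked candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
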