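Package: minppi
Title: Minimum Protein-Protein Interaction Sets Supporting Known Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the minimum number of protein-protein interactions that
    must be added to a (possibly empty) interaction network so that every protein
    complex in a given catalogue induces a connected subgraph. Provides an exact
    integer-linear-programming formulation based on a doubling encoding of
    reachability, with a CPLEX-dialect LP writer and a bundled exact
    branch-and-bound back end; a deterministic greedy approximation with
    rank-based confidence scores for the added interactions; seeded synthetic
    complex-catalogue generators; and evaluation utilities (score combination,
    confusion-matrix criteria, ROC/AUC) for comparing augmented networks against
    gold-standard interaction sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    withr
Config/testthat/edition: 3
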