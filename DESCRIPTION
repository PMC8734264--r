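Package: knotAlign
Title: Pairwise RNA Sequence-Structure Alignment with Pseudoknot Support
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simultaneous sequence and secondary-structure alignment of RNA
    molecules. Each pairwise alignment is modelled as an integer linear
    program over an alignment graph whose vertical edges (lines) carry
    substitution scores and whose interaction edges carry base-pair
    probabilities; the program is solved by Lagrangian relaxation, with upper
    bounds from global alignment under a position-specific score matrix and
    lower bounds from a greedy maximum weighted matching with look-ahead.
    Because structure is represented as an arbitrary weighted interaction
    graph rather than a nested bracket tree, crossing base pairs
    (pseudoknots) are aligned natively. Includes readers for dot-bracket and
    base-pair probability matrices, writers for T-Coffee libraries, MAFFT
    pairwise blocks and aligned FASTA, sum-of-pairs and Matthews correlation
    evaluation metrics, and a seeded generator of synthetic RNA families with
    planted structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    Biostrings,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
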