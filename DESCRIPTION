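Package: rfplus
Title: Optimal Phylogenetic Tree Completion Under Robinson-Foulds Distance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Linear-time optimal completion of phylogenetic trees with
    missing taxa under the Robinson-Foulds (RF) distance. Implements
    one-tree completion for rooted and unrooted binary trees (the leaf set
    of one tree nested in the other), extraneous-clade-free and
    extraneous-split-free two-tree completion for partially overlapping
    leaf sets, completion-based RF(+) and restriction-based RF(-)
    distances, exhaustive brute-force reference solvers for verification
    on small instances, a synthetic instance generator, supertree
    input-tree ranking with discordant-pair classification, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
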