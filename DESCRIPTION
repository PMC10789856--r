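Package: ohnotime
Title: Relative Timing of Gene Duplications from Branch-Length Ratios
Version: 0.1.0
Authors@R: person("Repro", "Build", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the relative age of gene duplications (including
    whole-genome duplication ohnologues) on outgroup-rooted phylogenies via the
    bc/ab branch-length ratio: the path from the outgroup-split node (a) to the
    duplication node (b) against the mean path from the duplication node to the
    present-day paralogue tips (c). Ships the supporting stages so the whole
    analysis runs from plain text files: strict FASTA/Newick/TSV readers,
    pairwise-deletion protein and nucleotide distances (Poisson, gamma, Kimura,
    JC69, K2P, and maximum-likelihood distances under empirical amino-acid
    models), deterministic neighbour-joining with bootstrap support and
    outgroup rooting, local-synteny orthology scoring with explicit ambiguity
    flagging, and a continuous-time Markov sequence-evolution simulator that
    generates duplication scenarios with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
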