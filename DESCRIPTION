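Package: superboot
Title: Alignment-Uncertainty-Aware Bootstrap Support for Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Concatenates alternative multiple sequence alignments of the same
    sequences into a Super-MSA, draws bootstrap replicates that favour columns
    from the most divergent aligners (SBOOT, pSBOOT and wpSBOOT sampling
    schemes), and computes whole-topology and per-clade bootstrap supports.
    Includes evaluation machinery for bootstrap calibration studies:
    all-or-nothing loss, Robinson-Foulds decomposition into Type I and Type II
    errors, reduced bootstrap trees at support thresholds, true-positive
    ranking curves, rank-based AUC, and support-comparison contingency tables;
    plus a self-contained sequence-evolution simulator for generating test
    fixtures with a known true tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
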