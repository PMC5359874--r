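Package: glasstree
Title: Total-Evidence Parsimony and Mk-Model Ancestral State
    Reconstruction for Morphological Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative phylogenetics of taxa with sparse
    molecular sampling, built around the workflow used for glass sponges
    (Hexactinellida): maximum-parsimony analysis of discrete morphological
    matrices with implied weighting, total-evidence concatenation of
    recoded nucleotide and morphological characters, weighted
    morphology-based placement of unsequenced taxa onto a molecular
    reference tree, and maximum-likelihood ancestral-state reconstruction
    of binary characters under symmetric (Mk1) and asymmetric (aMk2)
    Markov models with ascertainment-bias correction. Includes NEXUS
    matrix input/output, Fitch/Hartigan and Sankoff parsimony scoring,
    heuristic tree search, consensus and character bootstrap, ensemble
    homoplasy indices, discrete-gamma Mk and GTR likelihoods, and a
    seeded synthetic-data generator that emulates the structure of the
    study data for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
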