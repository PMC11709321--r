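Package: mutselpop
Title: Mutation-Selection Fitness Landscapes and the Population-Scale
    Fate of Beneficial Non-Adaptive Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-scale inference of selection on protein-coding genes.
    At the phylogenetic scale, site-specific amino-acid fitness
    landscapes are estimated under a mutation-selection codon model
    (Halpern-Bruno fixation rates), giving every possible coding
    mutation a scaled selection coefficient S0 and a class (deleterious
    D0, nearly-neutral N0, or beneficial non-adaptive B0).  At the
    population scale, distributions of fitness effects are fitted by
    maximum likelihood to class-stratified site-frequency spectra under
    Poisson random field theory, optionally augmented with
    terminal-branch divergence.  Bayes' rule combines the two scales
    into precision and recall per class, including the proportion of
    beneficial mutations that are non-adaptive, P[B0|B].  A
    synthetic-data generator with known ground truth (landscape shifts,
    mispolarization, CpG-like hypermutability) supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
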