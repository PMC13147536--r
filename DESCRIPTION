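Package: arglmm
Title: Linear Mixed Models on Ancestral Recombination Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the ARG linear mixed model for quantitative traits: exact
    branch genetic-relatedness-matrix (GRM) vector products computed
    implicitly from a succinct tree sequence, stochastic average-information
    REML variance-component estimation with Haseman-Elston initialization
    and randomized (XTrace) trace estimation, and best linear unbiased
    prediction (BLUP) of genetic values.  Includes a coalescent simulation
    harness (via msprime), dense small-sample oracles, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with msprime and tskit, required only
    for coalescent simulation and reading .trees files.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
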