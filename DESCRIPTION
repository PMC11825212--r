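Package: rjmk
Title: Reversible-Jump MCMC for Multistate Trait Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian comparative analysis of discrete multistate characters
    on time-calibrated phylogenies. Implements the Mk (continuous-time Markov)
    model with Felsenstein pruning, marginal ancestral-state reconstruction,
    maximum-likelihood rate estimation, and a reversible-jump MCMC sampler
    over partitions of the transition rates into shared-value classes with an
    optional zero class, under gamma rate priors with uniform hyperpriors.
    Provides posterior-proportion Bayes-factor tests for stepping-stone
    transition pathways (with set-partition counting priors) and for
    ancestral-state dominance (with uniform-simplex priors), a Yule-tree and
    character simulator for calibration studies, and an end-to-end pipeline
    applied to a bundled dataset of myiasis-associated life-history traits
    in blowflies (Calliphoridae).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
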