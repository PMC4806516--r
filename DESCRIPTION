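Package: gtrspace
Title: Exhaustive Time-Reversible Nucleotide Substitution Model Testing
Version: 1.0.0
Authors@R:
    person("Model Space", "Maintainers", email = "maintainers@gtrspace.example.org",
           role = c("aut", "cre"))
Description: Enumerates the complete space of 203 time-reversible nucleotide
    substitution models by two independent algorithms (exhaustive
    normalize-and-filter enumeration and an inductive derivation over
    rate-class refinements), scores every model by maximum likelihood with
    discrete-Gamma rate heterogeneity on a fixed randomized stepwise-addition
    parsimony tree, selects best-fit models under five information-criterion
    variants (AIC, AICc and BIC with two sample-size definitions), runs
    nearest-neighbour-interchange maximum-likelihood tree searches under the
    winning models, and quantifies the topological consequences via relative
    Robinson-Foulds distances with a permutation-based significance test.
    Includes a sequence-evolution simulator for model- and topology-recovery
    experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
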