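Package: mscbench
Title: Simulation Machinery and Scaling Analysis for Multispecies Coalescent Species Tree Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates species trees under Yule and birth-death models, gene
    trees under the multispecies coalescent, and nucleotide alignments under
    JC/HKY/GTR+Gamma strict-clock models; computes species-tree accuracy
    metrics (rooted branch score, relative species tree error, rooted
    Robinson-Foulds, pendant-edge bias) and the post hoc tree and alignment
    statistics used to explain residual variation in Bayesian MCMC
    performance; and fits and evaluates the power-law scaling models that
    relate effective sample size rates and species tree error to the number
    of loci, species and individuals sampled.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
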