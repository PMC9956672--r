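Package: rjadmix
Title: Bayesian Inference of Admixture Graphs by Reversible-Jump MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Samples the posterior distribution of admixture graphs --
    directed acyclic population histories with divergence and admixture
    nodes -- from multi-population biallelic allele-count data. Allele
    frequency change along branches follows a Gaussian drift model, so a
    graph implies a covariance matrix of outgroup-centered allele
    frequencies; the data enter through an empirical covariance matrix
    with a finite-sample bias correction and a Wishart likelihood whose
    degrees of freedom are estimated by block bootstrap. A reversible-jump
    Metropolis-coupled MCMC explores graphs with varying numbers of
    admixture events under a geometric prior on the event count and a
    uniform prior over labeled topologies evaluated with an exact counting
    recurrence. Posterior samples are summarized as highest-posterior
    graphs, descendant-set (clade) frequencies, consensus graphs at a
    frequency threshold, and posterior distributions of minimal topologies
    restricted to focal population subsets. A synthetic-data generator
    simulates allele counts from a known graph for calibration and
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
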