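Package: lambdaskyline
Title: Effective Population Size and Beta-Coalescent Inference from
    Multifurcating Genealogies
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian nonparametric inference of the effective
    population size trajectory Ne(t) and the Beta-coalescent parameter
    alpha from a rooted, timed multifurcating genealogy under the
    Lambda-coalescent.  Provides the merger-rate algebra for general
    base measures on [0,1] (Kingman, star, Beta, user discrete or
    continuous), the heterochronous variable-Ne coalescent likelihood,
    an intrinsic Gaussian Markov random field skyline prior on log
    Ne(t), a block-size pseudo-likelihood estimator of alpha, a hybrid
    Laplace estimator, a Metropolis-within-Gibbs sampler with split
    Hamiltonian Monte Carlo for the latent field, and a genealogy
    simulator supporting variable Ne(t) and serially sampled tips.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
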