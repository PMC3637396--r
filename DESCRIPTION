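Package: lexigeo
Title: Bayesian Spatiotemporal Phylogeography of Lexical Cognate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint Bayesian inference of time-calibrated language phylogenies
    and ancestral geographic locations from binary cognate presence/absence
    matrices. Implements a stochastic Dollo likelihood with ascertainment-bias
    correction, strict and lognormal relaxed clocks, a Bayesian skyline
    coalescent tree prior, and a relaxed random walk model of geographic
    diffusion with branch-specific rate scalars (Cauchy, gamma, or lognormal)
    and a land-only prior on ancestral locations. Includes stepping-stone
    marginal-likelihood estimation for Bayes-factor model choice, posterior
    summaries (maximum clade credibility trees, HPD intervals and location
    polygons), a homeland region Bayes-factor test, a tip-location
    randomization control, quartet-based tree-likeness statistics (delta
    score, Q-residual), a Swadesh-criterion intelligibility estimate, and a
    coalescent-plus-Dollo synthetic data generator with optional horizontal
    transfer for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
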