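Package: mosaicbrain
Title: Phylogenetic Comparative Tests of Mosaic Brain Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether brain components evolve in a mosaic
    fashion across a phylogeny: maximum-likelihood phylogenetic generalized
    least squares with Pagel's lambda, phylogenetic t-tests for clade grade
    shifts, a Gaussian phylogenetic mixed model ("animal model") over
    individual-level measurements sampled by Gibbs MCMC with
    parameter-expanded priors, and a reversible-jump variable-rates
    Brownian-motion model with stepping-stone marginal likelihoods and
    Bayes factors. Includes tree splicing/rescaling utilities, dataset
    assembly (species means, rest-of-brain construction, exclusion rules),
    an ecological-association suite, and synthetic-data generators that
    emulate the assumed evolutionary model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools
Config/testthat/edition: 3
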