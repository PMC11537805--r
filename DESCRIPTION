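Package: xlinksel
Title: Fitness Component Analysis for Two X-Linked Alleles in
    Experimental Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic selection recursions for one X-linked locus with
    two alleles, tracking hemizygous male and diploid female genotype
    frequencies over discrete non-overlapping generations, together with the
    inference pipeline used in multi-generation allelic-competition
    experiments: viability-ratio estimation from generation-2 adult counts,
    grid-search maximum-likelihood estimation of sex-specific fertility
    ratios from a composite binomial likelihood, profile-likelihood
    confidence intervals, and derivation of the six sex-specific fitness
    differences between two gene variants.  Includes a synthetic
    experimental-population generator (binomial observation noise around the
    deterministic trajectory, or finite-population drift) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
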