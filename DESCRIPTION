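Package: crossel
Title: Genomic Cross-Selection Simulation for Multi-Trait Recurrent Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of a recurrent-selection breeding program
    (crossing block, F1, doubled haploids, nursery, preliminary and advanced
    yield trials) driven by a multi-trait rank summation index used as a
    derived phenotype in whole-genome regression. Implements Bayesian ridge
    regression by Gibbs sampling, genomic estimated breeding values, and
    cross-usefulness metrics for selecting parent pairs: posterior
    mean-variance of progeny (PMV), the usefulness criterion (UC), optimal
    haploid value (OHV), mean parental GEBV with a Rogers-distance prefilter,
    and a random-mating baseline. Includes a founder-genome generator with
    linkage-disequilibrium structure, a Haldane-map meiosis engine, trait
    calibration to target means and variances, and treatment-grid experiment
    drivers for resource-allocation studies (number of parents, crosses and
    progeny per cross).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
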