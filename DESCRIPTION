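Package: crossBLUP
Title: Single-Step Genomic BLUP Evaluation of Crossbred Populations with
    Simulated Breeding Designs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time simulation of a two-purebred-line plus F1
    crossbred livestock system (deep historical population with bottlenecks,
    BLUP truncation selection within lines, four F1 cohorts) together with the
    genomic evaluation machinery needed to study crossbred prediction:
    pedigree (A) and VanRaden genomic (G) relationship matrices, the blended
    single-step H-inverse with tau/omega scaling factors, single- and
    three-trait mixed-model solvers, AI-REML variance-component estimation,
    iterative SNP weighting (weighted single-step GBLUP), genotype quality
    control, population-connectedness diagnostics (PCA of G, linkage
    disequilibrium, consistency of gametic phase, allele-frequency
    correlations), and an experiment driver for training-population scenarios
    and the tau/omega grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
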