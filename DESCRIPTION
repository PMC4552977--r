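Package: rrgsim
Title: Stochastic Simulation of Reciprocal Recurrent (Genomic) Selection in
    Heterotic Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of a two-population hybrid breeding
    program for a multiplicative trait (bunch production in oil palm, the
    product of bunch weight and bunch number). Provides a neutral
    Wright-Fisher style genome simulator with recombination and mutation,
    a bivariate pleiotropic QTL architecture with negatively correlated
    effects, a stylized population history producing two calibrated
    heterotic founder populations, pedigree/genomic/single-step
    relationship matrices, bivariate mixed-model (BLUP) machinery with an
    optional EM-REML path, and a four-cycle breeding-scheme engine
    comparing reciprocal recurrent selection against reciprocal recurrent
    genomic selection with parental or hybrid genotyping. Calibration and
    outcome statistics include Weir-Cockerham Fst, linkage-disequilibrium
    decay, selection accuracy, additive variances, genetic correlation and
    pedigree inbreeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR
VignetteBuilder: knitr
Config/testthat/edition: 3
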