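Package: thetaGWAS
Title: Continuous-Genotype Association Analysis for Polyploid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association analysis for even-ploidy crops using continuous
    genotype values (theta, the log2 contrast of the two allele signal
    intensities of an array probe) instead of called genotype classes.
    Provides signal transformation and segregation filtering, deregressed
    estimated breeding values from a REML-fitted mixed model, three
    association engines (per-probe linear regression with q-values,
    Bayesian variable selection with a two-component normal mixture prior
    sampled by Gibbs, and partial least squares regression with
    cross-validated latent-variable selection and variable-importance
    scoring), a naive nearest-centre genotype caller as a class-based
    comparator, and a polysomic F1 meiosis simulator (bivalent pairing,
    Haldane map function) that generates genotypes, allele intensities
    and phenotypes with known causal architecture for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    limma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
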