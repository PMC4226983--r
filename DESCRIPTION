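Package: seqimp
Title: Genotype Imputation to Sequence Density with Per-SNP Reliability
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluation of reference-based genotype imputation from
    low-density SNP panels up to sequence density, on simulated data with
    controllable linkage-disequilibrium structure. Provides a discrete
    Wright-Fisher haplotype simulator, minor-allele-frequency-ascertained
    nested marker panels, five-fold cross-validation scenario designs
    (including two-step imputation with disjoint reference sets), a diploid
    Li-Stephens haplotype-copying hidden Markov model producing posterior
    genotype probabilities and B-allele dosages, correlation-based accuracy
    metrics per SNP and per individual, and a multiplicative per-SNP
    reliability model combining linkage-disequilibrium decay with distance,
    an allele-frequency-difference upper bound, and an empirical
    Michaelis-Menten term for minor allele frequency and reference size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    minpack.lm,
    stats,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
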