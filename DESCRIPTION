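Package: aimpanel
Title: Ancestry Inference with Ancestry-Informative INDEL Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for compact panels of ancestry-informative
    insertion/deletion markers (AIM-INDELs) genotyped as biallelic (rarely
    triallelic) length polymorphisms. Reads and writes STRUCTURE-format
    genotype matrices; computes marker informativeness statistics (allele
    frequencies, delta differentials, Weir-Cockerham F_ST), Hardy-Weinberg
    exact tests and permutation-based linkage-disequilibrium tests; fits the
    admixture model by Gibbs sampling with independent or correlated cluster
    allele frequencies, supervised (population-flag) training, a log
    probability-of-data diagnostic for choosing the number of clusters, and
    cross-run cluster-label alignment; performs naive-Bayes population
    assignment with likelihood ratios and leave-one-out cross-validation;
    and runs principal component analysis on allele-dosage matrices. A
    genotype simulator generates admixed cohorts with controllable allele
    frequency differentials so every stage of the analysis can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
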