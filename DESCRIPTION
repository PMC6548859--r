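Package: spudgs
Title: Genomic Selection in Autotetraploid Potato from Transcriptome-Based Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline from tetraploid sequencing read
    counts to genomic-selection prediction accuracies. Calls five-class allele
    dosage genotypes (AAAA..BBBB, coded as reference-allele frequency) from
    ref/alt read depths, applies depth, alternate-support, missingness and
    minor-allele-frequency filters, imputes missing genotypes with a linkage
    disequilibrium k-nearest-neighbour method, fits BayesA and BayesB
    whole-genome regression by Gibbs sampling, evaluates cross-validated
    prediction accuracy and bias, and summarises genetic diversity with Nei's
    standard distance and a neighbour-joining tree. Includes a synthetic
    tetraploid cohort generator with known truth so every stage can be
    validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    jsonlite,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
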