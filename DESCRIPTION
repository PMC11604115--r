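Package: metapopdiv
Title: Diversity-Reservoir Analysis of Structured SNP Metapopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Partitions the gene diversity and rarefacted allelic richness of
    a SNP-genotyped metapopulation into within- and between-subpopulation
    components (HT = HS + DG, AT = AS + DA), computes each subpopulation's
    marginal (leave-one-out) contribution to every component against a
    retained outgroup, estimates contemporary effective population size per
    subpopulation by the linkage-disequilibrium and molecular-coancestry
    methods with jackknife confidence intervals, and provides the downstream
    structure and association statistics (genotype PCA, contribution-sign
    classification, Cochran-Mantel-Haenszel tests, rank and product-moment
    correlations). Includes seeded Balding-Nichols and Wright-Fisher
    simulators so the whole analysis is exercisable on synthetic genotypes
    with known structure, plus PLINK text PED/MAP input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
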