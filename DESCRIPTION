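Package: lowdense
Title: Genomic Selection with Low-Density Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for implementing genomic selection with low-density SNP
    panels in livestock populations where selection candidates have
    high-density genotyped sires but ungenotyped dams. Provides LD-based
    approximation of unknown marker positions via genotype-correlation
    equivalence classes, greedy design of low-density panels that balance
    marker informativeness against genome coverage, pedigree-aware imputation
    from low to high density using sire haplotypes and a
    relationship-weighted haplotype library, direct genomic value estimation
    by GBLUP with heterogeneous residual variances, imputation error and
    accuracy metrics, and a regression approach that corrects
    cross-validation accuracies for correlated prediction errors. Includes a
    gene-dropping simulator that generates pedigree-structured test
    populations with the assumed family design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
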