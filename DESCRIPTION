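Package: gwps
Title: Genome-Wide Predictive Studies with MeanDiff Feature Selection and
    Nested Cross-Validated KNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide predictive studies (GWPS) of case-control
    single-nucleotide-polymorphism (SNP) genotype data. Implements SNP-level
    quality control (missing-call, Hardy-Weinberg equilibrium and minor allele
    frequency filters), MeanDiff univariate feature ranking, a k-nearest
    neighbour classifier over genotype codes, internal cross-validated
    selection of the neighbour count (BestKNN), correctly nested leave-one-out
    cross-validation alongside the deliberately biased non-nested variant that
    demonstrates feature-selection leakage, and permutation-based significance
    testing of classifier accuracy. Ships a seeded synthetic case-control
    genotype simulator with planted effect SNPs and injectable quality-control
    violations so the whole pipeline is testable without cohort data, plus
    readers and writers for a simple tab-separated genotype format and VCF
    import.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
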