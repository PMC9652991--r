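Package: snpdemog
Title: SNP Population Genomics and Joint Allele-Frequency-Spectrum Demographic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of reduced-representation
    SNP data in structured, hybridizing populations: quality-control filtering
    of DArT-style SNP matrices, diversity and differentiation statistics
    (observed/expected heterozygosity, FIS, rarefied allelic richness,
    Weir-Cockerham FST, AMOVA and sequence PhiST), FDIST-style coalescent
    outlier scans with FDR control, maximum-likelihood admixture
    (ancestry-proportion) inference with cross-validated choice of K,
    NewHybrids-style Bayesian classification of hybrid categories, and
    two-population demographic inference from the folded joint allele
    frequency spectrum (secondary-contact and asymmetric-migration model
    family, Poisson composite likelihood, AIC model selection, rejection-ABC
    cross-check, and conversion of scaled parameters to biological units).
    A structured-coalescent simulation engine generates all test inputs:
    genotypes under the demographic model family, hybrid swarms, island-model
    neutral loci, mtDNA-like haplotype alignments, and pre-QC fixtures with
    planted filter violations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
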