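Package: cardase
Title: Allele-Specific and Loss-of-Expression Analysis for Cardiovascular RNA-seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects extreme allele-specific expression (ASE) and biallelic
    loss-of-expression (LOE) in RNA-seq cohorts genotyped at heterozygous
    SNPs. Implements a quality-control cascade for subjects, SNPs and genes;
    a compound allele-ratio statistic combining trio-phased and
    higher-allele-assigned unphased SNPs with an exact binomial test and
    per-sample Bonferroni correction; assessment of genomic imprinting and
    nonsense-mediated decay; leave-one-out expression-outlier calling by
    fold change and z-score within tissue groups; and a synthetic cohort
    generator with injected truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
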