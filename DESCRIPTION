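Package: raddose
Title: Species and Ploidy Inference for Hybridogenetic Water Frogs from
    ddRAD Allele Depths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic monitoring of Pelophylax water frog
    complexes in which the hybrid klepton P. kl. esculentus coexists with
    its parental species. Implements a complete pipeline from raw ddRAD
    reads to pond-level breeding-system classification: PCR-duplicate
    removal using degenerate-base-region (DBR) tags, SNP and sample
    filtering, genotyping-error estimation from technical replicates,
    principal-component ordination and ancestry-threshold cluster
    assignment, discovery of loci diagnostic for the L (P. lessonae) and
    R (P. ridibundus complex) genomes, ploidy inference from allele-depth
    dosage at heterozygous diagnostic loci (LL, LR, LLR, LRR, RR), rapid
    species calls from the 33-bp MND1 nuclear marker and ND1
    mitochondrial haplogroups, and breeding-system classification of
    ponds (L-E, modified L-E, all-hybrid candidates). A synthetic-data
    generator emulates biallelic RAD loci with binomial allele-depth
    dosage, DBR-tagged read pairs and marker sequences, so every step of
    the pipeline can be exercised and validated without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
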