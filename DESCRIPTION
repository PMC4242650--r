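Package: tropigwas
Title: Admixture-Aware GWAS Toolkit for Tropically Adapted Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative-genetics pipeline for genome-wide association in
    admixed taurine x indicine cattle populations: supervised ancestry
    proportion estimation from two reference panels, animal-model REML
    heritability with genomic or pedigree relationship matrices, single-SNP
    mixed-model association with polygenic control, per-SNP genetic-variance
    partitioning, an explicit false-discovery-rate estimator, a multi-trait
    pleiotropy test on studentized SNP effects, divergent-allele scoring, and
    a synthetic admixed-cohort generator emulating a crossbred half-sib
    design for end-to-end validation.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
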