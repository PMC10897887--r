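Package: electroase
Title: Differential, Duration-Associated and Allele-Specific Expression in
    Electric Fish Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for electric organ (EO) versus skeletal muscle
    (SM) bulk RNA-seq in mormyrid electric fish and their F1 hybrids.
    Implements per-cohort negative-binomial differential expression with a
    Wald test and cross-cohort intersection of shared DEGs, detection of
    genes whose EO expression tracks electric organ discharge (EOD) duration
    via an interaction likelihood-ratio test followed by expression-pattern
    clustering, and allele-specific expression analysis in F1 hybrids from
    fixed parental SNPs in a multi-sample VCF, with allelic-imbalance
    classification. A seeded synthetic-data generator emulates the cohort
    structure, planted tissue and duration effects, and allelic read counts,
    so every stage can be exercised and calibrated without the deposited
    sequencing reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    seqinr,
    optparse
Config/testthat/edition: 3
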