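Package: pwascreen
Title: Proteome-Wide Analysis of Disease-Associated SNP Pulldown Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for proteome-wide analyses of disease-associated SNPs
    (PWAS): paired reference/alternate-allele DNA-pulldown quantification
    tables are combined across dimethyl label-swap replicates, batch
    corrected, imputed, and screened for allele-specific protein binders
    with an intensity-binned ratio-outlier test; candidate SNP-TF
    interactions are then prioritized by a combined z-score of locus DNase I
    hypersensitivity and binding fold change. Companion utilities provide
    exact-test allelic-imbalance summaries at heterozygous SNPs and 4C-seq
    reduced-genome construction (in-silico restriction digestion, flank
    extraction, uniqueness filtering) with windowed interaction counting.
    A synthetic-data generator with a ground-truth ledger makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
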