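Package: tipscan
Title: Transposon Insertion Polymorphisms, cis-eQTL Mapping and Selection Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links transposon insertion polymorphisms (TIPs) to gene expression
    variation and to signatures of selection in structured plant populations.
    Provides filtering, binarization and imputation of TIP zygosity matrices;
    per-replicate cis TIP- and SNP-eQTL mapping with subpopulation covariates
    and Benjamini-Hochberg false discovery control; per-locus Population Branch
    Statistic scans across three populations with Hudson FST; and locus-level
    sweep scans (windowed nucleotide diversity and H12 haplotype homozygosity,
    carriers versus non-carriers) against permutation nulls. A synthetic-cohort
    generator with Balding-Nichols frequency differentiation, planted cis
    expression effects and planted sweeps makes every stage testable without
    external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
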