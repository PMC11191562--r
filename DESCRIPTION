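Package: macroCRE
Title: Cis-Regulatory Element Mapping and GWAS Heritability Partitioning
    from Single-Cell Multiome Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links paired single-cell RNA and ATAC profiles to GWAS
    genetics. Discovers cis-regulatory elements (CREs) by correlating peak
    accessibility with expression of genes within 500 kb against
    GC- and accessibility-matched background nulls, calls domains of
    regulatory chromatin (DORCs), computes chromVAR-style per-cell TF
    motif deviation scores, scores signed TF-DORC regulatory interactions,
    prioritizes GWAS variants through LD expansion and CRE overlap with a
    matched-background permutation test, and partitions SNP heritability
    across weighted gene programs via stratified LD-score regression with
    block-jackknife standard errors. A synthetic-data module generates
    multiome counts, block-LD haplotype panels and GWAS summary statistics
    with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
biocViews: SingleCell, Epigenetics, GenomeWideAssociationStudies,
    GeneRegulation, ATACSeq, RNASeq, Software
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'deviations.R'
    'gwas.R'
    'heritability.R'
    'io.R'
    'linking.R'
    'macroCRE-package.R'
    'network.R'
    'normalize.R'
    'pipeline.R'
    'simulateGwas.R'
    'simulateMultiome.R'
    'utils.R'
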