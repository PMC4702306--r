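Package: bsaqtl
Title: Pooled-Segregant and Individual-Segregant QTL Mapping for Yeast Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTLs) from
    phenotype-selected segregant pools and from individually sequenced
    segregants of a haploid yeast cross. Implements SNP variant-frequency
    linkage mapping from pooled allele depths (quality filtering, kernel
    smoothing with confidence bands against the Mendelian 0.5 expectation,
    exact binomial linkage tests, unselected-pool subtraction) and a
    Kullback-Leibler parent-of-origin pipeline for individual segregants
    (genotype distributions, divergence-based assignment, per-segregant
    false-discovery-rate filtering, Gaussian track smoothing, 3-kb window
    calls, phenotype-ordered averaging and threshold QTL calling). A seeded
    forward simulator of meiosis, multi-round random-spore inbreeding,
    polygenic phenotypes, truncation selection and pooled or individual
    short-read allele counts provides ground-truth data for validating both
    engines. Includes interval reporting, gene annotation of mapped regions,
    and file adapters for TSV, VCF, BED and GFF3.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    methods,
    Matrix,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
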