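Package: aselnc
Title: Allele-Specific Expression Mapping of cis-Regulatory SNPs for lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps cis-acting regulatory SNPs (cis-rSNPs) for long non-coding
    RNA regions from two-channel SNP-array genotyping of paired genomic DNA
    and cDNA. Implements binned-median quadratic intensity normalization of
    allele fractions, genotype- and sample-level quality control
    (call-rate, Hardy-Weinberg, cDNA contamination), phase-oriented
    per-SNP and per-window allele-specific expression (ASE),
    linear-regression association of window ASE with phased candidate-SNP
    genotypes, replicate-consensus enhancer-peak construction with
    fold-enrichment testing, lncRNA/protein-coding co-expression
    classification under FDR control, and overlap of cis-rSNPs with a
    GWAS-catalog table directly and through LD proxies. Ships a
    synthetic-data generator with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
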