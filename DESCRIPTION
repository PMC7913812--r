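Package: csslqtl
Title: Segment Maps, QTL Scans and Candidate-Gene Triage for Chromosome
    Segment Substitution Line Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing chromosome segment substitution line (CSSL)
    populations genotyped by low-coverage resequencing: QC filtering of SNP
    genotype matrices, recombination-breakpoint inference and donor-segment
    calling per line, construction of SNP linkage-disequilibrium block
    (SNPLDB) marker maps from the population-wide breakpoint union,
    physical-map statistics and map comparison, bulk-segregant co-segregation
    mapping of qualitative traits with the phenotype-genotype consistency
    statistic, a stepwise-regression likelihood-ratio additive QTL scan
    (LOD, additive effect, PVE) with multi-environment heritability,
    rule-based candidate-gene triage from parental expression tables and
    variant-effect classification, and background-matched haplotype-effect
    contrasts. Includes a seeded simulator of backcross-derived CSSL
    populations, phenotypes, expression tables and planted causal variants
    for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
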