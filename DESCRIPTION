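Package: sweqtl
Title: Expression GWAS and eQTL Annotation for Multi-Tissue RNA-Seq Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for expression quantitative trait locus (eQTL)
    discovery from genotype and bulk RNA-seq data: genotype quality control,
    TMM/log2-cpm expression normalization with a Shapiro-Wilk leave-one-out
    outlier screen, per-gene mixed linear model association scans against a
    genomic relationship matrix with Bonferroni adjustment, clustering of
    significant variants into cis/trans eQTL regions, detection of hotspot
    and top-hotspot regulatory polymorphisms, PCIT (partial correlation and
    information theory) coexpression assessment of putative regulator genes,
    and position weight matrix scanning of SNP-context sequences with exact
    p-values. Includes a synthetic-data generator that emulates a
    multi-breed study design with planted cis, trans and hotspot-mediated
    effects so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    edgeR,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
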