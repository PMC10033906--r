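Package: cisplice
Title: Discovery of Cis-Acting Splice-Associated Variants in RNA-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates somatic variant calls (VCF) with splice junctions
    observed in RNA-seq alignments to identify cis-acting splice-associated
    variants. Annotates variants by their distance to exon edges under a
    configurable splice-variant window, extracts exon-exon junctions from
    CIGAR skipped regions, classifies junctions against a reference
    transcriptome (DA/NDA/D/A/N), associates junctions with variants through
    per-variant splice-junction regions, scores variant-junction events
    across a cohort with an empirical junction-usage statistic under
    Benjamini-Hochberg FDR control, and ranks genes for recurrent splice
    disruption with a binomial model over each gene's splice-variant-window
    footprint. Ships a synthetic-data generator (reference genome,
    transcript models, cohorts of reads and variant calls) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    jsonlite
Config/testthat/edition: 3
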