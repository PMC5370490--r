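Package: numtquant
Title: Quantification of Nuclear Mitochondrial DNA Insertions from
    Paired-End Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects mito-nuclear chimeric read pairs (NUMT-supporting
    discordant pairs) in matched tumor and blood-derived-normal paired-end
    alignment files, quantifies relative NUMT abundance normalized to mapped
    read count over nested genomic partitions (genome, chromosome, arm,
    cytoband, sliding window; mitochondrial genome, strand, gene), computes
    rescaled tumor-versus-normal fold changes with plate-pooled baselines for
    sparse partitions, runs cohort-level statistics (paired and two-sample
    tests on log-transformed proportions, tumor-on-blood regression,
    stratified summaries, GC and Giemsa-band association), locates
    mitochondrial fragile sites and tumor-unique numtogenesis regions, and
    ships a synthetic matched-cohort simulator with full ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    IRanges,
    GenomicRanges,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
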