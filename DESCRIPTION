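Package: tgstab
Title: Transgene Integration-Site Calling and Genomic Stability
    Assessment from Whole-Genome Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for characterizing transposon-derived
    transgenic genomes from short-read whole-genome sequencing.  Detects
    transposon (Sleeping Beauty / piggyBac) integration sites from
    soft-clipped alignments with target-site-duplication (TA / TTAA)
    resolution and flanking-gene annotation; classifies trio genotypes by
    allele-depth ratio and calls de novo mutations with repeat-artifact
    flagging and positional annotation; scans read depth in fixed genomic
    windows with GC-content normalization for copy-number changes;
    estimates telomere length from the frequency of TTAGGG-rich reads;
    and quantifies fluorescence images by ImageJ-style integrated
    density.  A full synthetic-data layer (genomes, construct insertions
    with duplicated target sites, paired-end reads with ground-truth
    alignments, trio depth tables, telomeric tracts, Dre-rox
    recombination products, and cell images) provides known truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
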