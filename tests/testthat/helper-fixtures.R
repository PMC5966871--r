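## Shared fixtures, built in code at test time.

## a minimal construct whose ends are easy to recognize by eye
toy_construct <- function(tsd = "TTAA") {
  withr::with_seed(42L, {
    transposon_construct("cons", tgstab:::random_dna(400), tsd_motif = tsd,
                         end_length = 40L)
  })
}

## a small host genome with a guaranteed motif occurrence per contig
toy_host <- function(motif = "TTAA", len = 12000L, n_contig = 1L,
                     seed = 7L) {
  withr::with_seed(seed, {
    g <- vapply(seq_len(n_contig), function(i) tgstab:::random_dna(len),
                character(1))
    names(g) <- paste0("chr", seq_len(n_contig))
    for (ct in names(g))
      g[[ct]] <- tgstab:::overwrite(g[[ct]], len %/% 2L, motif)
    g
  })
}

## read data.frame from raw vectors
make_reads <- function(seqs, quals = NULL, names = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(names)) names <- sprintf("r%03d", seq_along(seqs))
  data.frame(name = names, sequence = seqs, quality = quals, mate = 1L,
             stringsAsFactors = FALSE)
}

## quality string from integer scores
qstring <- function(scores) intToUtf8(scores + 33L)

## one-line trio site record
trio_site <- function(contig = "chr1", pos = 100L, sire = c(30L, 0L),
                      dam = c(30L, 0L), off = c(15L, 15L), gq = 99L) {
  data.frame(contig = contig, pos = pos, ref = "A", alt = "G",
             sire_ref = sire[1], sire_alt = sire[2],
             dam_ref = dam[1], dam_alt = dam[2],
             off_ref = off[1], off_alt = off[2],
             gq_sire = gq, gq_dam = gq, gq_off = gq,
             stringsAsFactors = FALSE)
}

## tiny gene model: gene A and B on chr1 with one exon each
toy_model <- function() {
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1"), IRanges::IRanges(c(1000L, 5000L), c(2000L, 6000L)),
    gene_id = c("A", "B"))
  exons <- GenomicRanges::GRanges(
    c("chr1", "chr1"), IRanges::IRanges(c(1000L, 5000L), c(1200L, 5200L)),
    gene_id = c("A", "B"))
  gene_model(genes, exons)
}
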