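#' Construct a gene model
#'
#' A gene model is a list of two [GenomicRanges::GRanges]: `genes` (one
#' range per gene, with a `gene_id` metadata column) and `exons` (one
#' range per exon, with the `gene_id` of its parent).  Every exon must
#' lie within its parent gene span.  Coordinates are 1-based inclusive
#' throughout (the GFF3 / Bioconductor convention).
#'
#' @param genes GRanges with `gene_id` metadata column.
#' @param exons GRanges with `gene_id` metadata column.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(genes, exons) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(exons, "GRanges"))
  if (is.null(genes$gene_id) || anyDuplicated(genes$gene_id))
    stop("genes must carry unique gene_id metadata")
  if (length(exons)) {
    if (is.null(exons$gene_id)) stop("exons must carry gene_id metadata")
    idx <- match(exons$gene_id, genes$gene_id)
    if (anyNA(idx)) stop("exon references unknown gene: ",
                         exons$gene_id[is.na(idx)][1])
    within <- as.character(GenomicRanges::seqnames(exons)) ==
                as.character(GenomicRanges::seqnames(genes))[idx] &
              GenomicRanges::start(exons) >= GenomicRanges::start(genes)[idx] &
              GenomicRanges::end(exons) <= GenomicRanges::end(genes)[idx]
    if (!all(within))
      stop("exon outside its parent gene span: ", exons$gene_id[!within][1])
  }
  structure(list(genes = genes, exons = exons), class = "gene_model")
}

#' Read a GFF3 gene model
#'
#' Parses `gene` and `exon` features from a GFF3 file (1-based inclusive
#' on disk, preserved internally) into a [gene_model()].
#'
#' @param path GFF3 file.
#' @return a `gene_model`.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  genes$gene_id <- if (!is.null(genes$ID)) as.character(genes$ID) else
    as.character(genes$Name)
  parent <- if (!is.null(exons$Parent)) {
    vapply(exons$Parent, function(p) as.character(p)[1], character(1))
  } else character(0)
  exons$gene_id <- parent
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = genes$gene_id)
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(gene_id = exons$gene_id)
  gene_model(genes, exons)
}

#' Write a gene model to GFF3
#'
#' @param model a [gene_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  g <- model$genes
  e <- model$exons
  gg <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                               IRanges::ranges(g),
                               strand = GenomicRanges::strand(g))
  gg$source <- "tgstab"; gg$type <- "gene"
  gg$ID <- g$gene_id; gg$Name <- g$gene_id
  ee <- GenomicRanges::GRanges(GenomicRanges::seqnames(e),
                               IRanges::ranges(e),
                               strand = GenomicRanges::strand(e))
  if (length(ee)) {
    ee$source <- "tgstab"; ee$type <- "exon"
    ee$ID <- sprintf("%s.exon%d", e$gene_id,
                     stats::ave(seq_along(e), e$gene_id, FUN = seq_along))
    ee$Parent <- as.character(e$gene_id)
    out <- c(gg, ee)
  } else out <- gg
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a BED interval file
#'
#' BED is 0-based half-open on disk; the returned GRanges follows the
#' 1-based inclusive Bioconductor convention (a BED line `chr1 0 50`
#' becomes `chr1:1-50`).
#'
#' @param path BED file.
#' @return a GRanges (with `name` metadata when the BED has 4+ columns).
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write intervals to a BED file
#'
#' @param gr a GRanges.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Intronic intervals of a gene
#'
#' The complement of a gene's exons within its span.
#'
#' @param model a [gene_model()].
#' @param gene_id gene identifier.
#' @return GRanges of introns (possibly empty).
#' @export
introns <- function(model, gene_id) {
  stopifnot(inherits(model, "gene_model"))
  g <- model$genes[model$genes$gene_id == gene_id]
  if (length(g) != 1) stop("unknown gene: ", gene_id)
  e <- model$exons[model$exons$gene_id == gene_id]
  GenomicRanges::setdiff(g, e, ignore.strand = TRUE)
}
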