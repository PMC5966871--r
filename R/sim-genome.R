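## Synthetic diploid-genome surrogate: random contigs with configurable
## GC, terminal TTAGGG tracts, planted TSD motifs, a small gene model
## and LTR-repeat annotation.  Serves as the known-truth reference that
## every downstream stage is validated against.

TELOMERE_MOTIF <- "TTAGGG"

overwrite <- function(seq, at, replacement) {
  ## replace bases of `seq` starting at 1-based `at` with `replacement`
  paste0(substr(seq, 1L, at - 1L), replacement,
         substr(seq, at + nchar(replacement), nchar(seq)))
}

telomere_tract <- function(len) {
  substr(strrep(TELOMERE_MOTIF, ceiling(len / 6) + 1L), 1L, len)
}

#' Build a synthetic annotated genome
#'
#' Generates random contigs at a target GC content, overwrites both ends
#' of each contig with phase-aligned TTAGGG telomere tracts, plants
#' extra copies of the requested TSD motif in the interior, and lays
#' down a small gene model (genes with exons) plus LTR-repeat intervals
#' per contig.
#'
#' @param contig_lengths named integer vector of contig lengths (each
#'   >= 10000).
#' @param gc target GC fraction of the random background.
#' @param tsd_motif motif to guarantee in the interior ("TTAA" or "TA").
#' @param tsd_density_per_kb planted motif copies per kb (in addition to
#'   chance occurrences).
#' @param telomere_tract_length length (bases) of the TTAGGG tract at
#'   each contig end; 0 disables telomeres.  Must be <= contig length / 2.
#' @param genes_per_contig number of genes annotated per contig.
#' @param seed RNG seed.
#' @return an object of class `synthetic_genome`: list with `genome`
#'   (named character vector), `genes` / `exons` (a [gene_model()]),
#'   `repeats` (GRanges of LTR intervals), and the build parameters.
#' @export
build_genome <- function(contig_lengths, gc = 0.5, tsd_motif = "TTAA",
                         tsd_density_per_kb = 0.2,
                         telomere_tract_length = 0L,
                         genes_per_contig = 2L, seed = 1L) {
  stopifnot(all(contig_lengths >= 10000L))
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  if (any(telomere_tract_length > contig_lengths / 2))
    stop("telomere tract longer than half a contig")
  withr::with_seed(seed, {
    genome <- vapply(contig_lengths, random_dna, character(1), gc = gc)
    names(genome) <- names(contig_lengths)
    ## terminal telomere tracts, phase-aligned at both ends
    if (telomere_tract_length > 0) {
      tr <- telomere_tract(telomere_tract_length)
      genome <- vapply(genome, function(s) {
        s <- overwrite(s, 1L, tr)
        overwrite(s, nchar(s) - telomere_tract_length + 1L, tr)
      }, character(1))
    }
    tel <- as.integer(telomere_tract_length)
    gene_list <- list(); exon_list <- list(); rep_list <- list()
    for (ct in names(genome)) {
      len <- contig_lengths[[ct]]
      lo <- tel + 1000L; hi <- len - tel - 1000L
      ## plant TSD motifs in the interior, clear of annotation edges
      n_motif <- ceiling(tsd_density_per_kb * len / 1000)
      if (n_motif > 0) {
        at <- sort(sample(seq(lo, hi - nchar(tsd_motif)), n_motif))
        ## drop planted motifs closer than 500 bp to each other
        at <- at[c(TRUE, diff(at) > 500)]
        for (p in at) genome[[ct]] <- overwrite(genome[[ct]], p, tsd_motif)
      }
      ## genes: evenly spaced spans, each with 2 exons
      ng <- genes_per_contig
      if (ng > 0) {
        span <- (hi - lo) %/% (2L * ng)
        gstart <- lo + (seq_len(ng) - 1L) * 2L * span + span %/% 2L
        gend <- gstart + span - 1L
        ids <- sprintf("%s_gene%d", ct, seq_len(ng))
        gene_list[[ct]] <- data.frame(contig = ct, start = gstart,
                                      end = gend, gene_id = ids)
        qlen <- span %/% 4L
        exon_list[[ct]] <- data.frame(
          contig = ct,
          start = c(gstart, gend - qlen + 1L),
          end = c(gstart + qlen - 1L, gend),
          gene_id = rep(ids, 2))
      }
      ## one LTR repeat interval per contig, between the last gene and
      ## the 3' telomere
      rstart <- hi - 2999L
      rep_list[[ct]] <- data.frame(contig = ct, start = rstart,
                                   end = rstart + 1999L)
    }
    gdf <- do.call(rbind, gene_list)
    edf <- do.call(rbind, exon_list)
    rdf <- do.call(rbind, rep_list)
    if (is.null(gdf)) {
      genes <- GenomicRanges::GRanges()
      genes$gene_id <- character(0)
      exons <- GenomicRanges::GRanges()
      exons$gene_id <- character(0)
    } else {
      genes <- GenomicRanges::GRanges(gdf$contig,
                                      IRanges::IRanges(gdf$start, gdf$end),
                                      gene_id = gdf$gene_id)
      exons <- GenomicRanges::GRanges(edf$contig,
                                      IRanges::IRanges(edf$start, edf$end),
                                      gene_id = edf$gene_id)
    }
    repeats <- GenomicRanges::GRanges(rdf$contig,
                                      IRanges::IRanges(rdf$start, rdf$end),
                                      name = "LTR")
    structure(list(genome = genome,
                   model = gene_model(genes, exons),
                   repeats = repeats,
                   telomere_tract_length = tel,
                   tsd_motif = tsd_motif,
                   seed = seed),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d contig(s), %s bp total, %d gene(s), %d repeat interval(s)\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
              length(x$model$genes), length(x$repeats)))
  invisible(x)
}

#' Plant transposon insertions with target-site duplication
#'
#' Models cut-and-paste integration: at a motif occurrence starting at
#' `tsd_start` (1-based) the modified contig becomes
#' `host[1..tsd_start+m-1] + construct + motif + host[tsd_start+m..]`,
#' i.e. the TSD motif ends up duplicated immediately on both sides of
#' the construct (reverse-complemented for reverse orientation).  Each
#' insertion lengthens the contig by `nchar(construct) + nchar(motif)`.
#'
#' @param genome a `synthetic_genome`, named character vector or
#'   DNAStringSet (the unmodified host reference).
#' @param construct a [transposon_construct()].
#' @param insertions data.frame with columns `contig`, `tsd_start`
#'   (1-based position of the motif occurrence in *reference*
#'   coordinates) and `orientation` (`"forward"`/`"reverse"`).
#' @return an object of class `planted_genome`: list with `reference`
#'   (unmodified host), `modified` (host with insertions), `construct`,
#'   `truth` (the insertion ledger in reference coordinates), `segments`
#'   (per-contig piecewise coordinate map used by the truth aligner) and
#'   the annotation carried over from a `synthetic_genome` input.
#' @export
plant_insertions <- function(genome, construct, insertions) {
  stopifnot(inherits(construct, "transposon_construct"))
  annotation <- NULL
  if (inherits(genome, "synthetic_genome")) {
    annotation <- genome[c("model", "repeats", "telomere_tract_length")]
    genome <- genome$genome
  }
  ref <- as_genome_chr(genome)
  motif <- construct$tsd_motif
  m <- nchar(motif)
  L <- nchar(construct$sequence)
  if (nrow(insertions)) {
    stopifnot(all(c("contig", "tsd_start", "orientation") %in% names(insertions)))
    if (!all(insertions$contig %in% names(ref)))
      stop("insertion on unknown contig: ",
           setdiff(insertions$contig, names(ref))[1])
    if (!all(insertions$orientation %in% c("forward", "reverse")))
      stop("orientation must be 'forward' or 'reverse'")
    found <- substr(ref[insertions$contig], insertions$tsd_start,
                    insertions$tsd_start + m - 1L)
    if (any(found != motif))
      stop(sprintf("no %s motif at %s:%d (found '%s')", motif,
                   insertions$contig[found != motif][1],
                   insertions$tsd_start[found != motif][1],
                   found[found != motif][1]))
    insertions <- insertions[order(insertions$contig, insertions$tsd_start), ,
                             drop = FALSE]
    for (ct in unique(insertions$contig)) {
      p <- insertions$tsd_start[insertions$contig == ct]
      if (length(p) > 1 && any(diff(p) <= m))
        stop("insertions overlap on contig ", ct)
    }
    rownames(insertions) <- NULL
  }
  modified <- ref
  segments <- list()
  for (ct in names(ref)) {
    ins <- insertions[insertions$contig == ct, , drop = FALSE]
    segs <- build_segments(nchar(ref[[ct]]), ins$tsd_start, ins$orientation,
                           m, L)
    segments[[ct]] <- segs
    if (nrow(ins)) {
      ## apply right-to-left so earlier reference coordinates stay valid
      s <- ref[[ct]]
      blocks <- ifelse(ins$orientation == "forward",
                       construct$sequence, revcomp(construct$sequence))
      for (i in rev(seq_len(nrow(ins)))) {
        p <- ins$tsd_start[i]
        s <- paste0(substr(s, 1L, p + m - 1L), blocks[i],
                    substr(s, p, nchar(s)))
      }
      modified[[ct]] <- s
    }
  }
  structure(list(reference = ref, modified = modified, construct = construct,
                 truth = insertions, segments = segments,
                 annotation = annotation),
            class = "planted_genome")
}

#' @rdname plant_insertions
#' @param contig,tsd_start,orientation single-insertion shorthand.
#' @export
plant_insertion <- function(genome, construct, contig, tsd_start,
                            orientation = "forward") {
  plant_insertions(genome, construct,
                   data.frame(contig = contig, tsd_start = tsd_start,
                              orientation = orientation,
                              stringsAsFactors = FALSE))
}

## Piecewise map from modified-contig coordinates to (host | construct)
## coordinates.  Host reference positions p..p+m-1 (the TSD) appear
## twice in the modified contig, exactly as a real aligner sees them.
## Columns: mod_start, mod_end, type ("host"/"construct"), offset
## (host = mod - offset) or block_start/orient for construct segments.
build_segments <- function(contig_len, tsd_starts, orientations, m, L) {
  segs <- data.frame(mod_start = integer(0), mod_end = integer(0),
                     type = character(0), offset = integer(0),
                     block_start = integer(0), orient = character(0),
                     stringsAsFactors = FALSE)
  mod_cursor <- 1L   # next modified coordinate to assign
  host_cursor <- 1L  # host coordinate mapped to mod_cursor
  shift <- 0L        # cumulative inserted length
  for (i in seq_along(tsd_starts)) {
    p <- tsd_starts[i]
    ## host segment up to and including the motif at p..p+m-1
    host_end <- p + m - 1L
    seg_len <- host_end - host_cursor + 1L
    segs <- rbind(segs, data.frame(
      mod_start = mod_cursor, mod_end = mod_cursor + seg_len - 1L,
      type = "host", offset = shift, block_start = NA_integer_,
      orient = NA_character_))
    mod_cursor <- mod_cursor + seg_len
    ## construct block of length L
    segs <- rbind(segs, data.frame(
      mod_start = mod_cursor, mod_end = mod_cursor + L - 1L,
      type = "construct", offset = NA_integer_, block_start = mod_cursor,
      orient = orientations[i]))
    mod_cursor <- mod_cursor + L
    ## host resumes at p (duplicated motif)
    host_cursor <- p
    shift <- mod_cursor - host_cursor
  }
  segs <- rbind(segs, data.frame(
    mod_start = mod_cursor, mod_end = mod_cursor + (contig_len - host_cursor),
    type = "host", offset = shift, block_start = NA_integer_,
    orient = NA_character_))
  rownames(segs) <- NULL
  segs
}

#' @export
print.planted_genome <- function(x, ...) {
  cat(sprintf("<planted_genome> %d contig(s), %d planted insertion(s) of %s\n",
              length(x$reference), nrow(x$truth), x$construct$name))
  invisible(x)
}
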