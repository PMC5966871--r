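## Transgene integration-site detection from soft-clipped alignments.
## A read whose alignment to the host genome ends in a soft clip, with
## the clipped tail matching a construct end at high identity, marks an
## integration junction; clustered junction evidence yields a call with
## TSD, orientation, read support and flanking genes.

## ungapped identity between the aligned prefixes/suffixes of two strings
ungapped_identity <- function(a, b, from = c("start", "end")) {
  from <- match.arg(from)
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(c(identity = 0, overlap = 0))
  if (from == "start") {
    x <- substr(a, 1L, n); y <- substr(b, 1L, n)
  } else {
    x <- substr(a, nchar(a) - n + 1L, nchar(a))
    y <- substr(b, nchar(b) - n + 1L, nchar(b))
  }
  xa <- strsplit(x, "")[[1]]; ya <- strsplit(y, "")[[1]]
  c(identity = mean(xa == ya), overlap = n)
}

#' Extract soft-clip junction evidence from alignments
#'
#' Scans host-mapped, non-duplicate alignments for terminal soft clips of
#' at least `min_clip_length` bases whose clipped sequence matches a
#' construct end by ungapped identity (a deliberate simplification of
#' local alignment: junction tails from real integrations are exact or
#' near-exact copies of the construct terminus).
#'
#' Matching geometry: a *right* clip (clip after the matched block) is
#' compared read-outward from the junction, i.e. against the start of
#' the construct (`left` end, forward insertion) or the start of its
#' reverse complement (`right` end, reverse insertion); a *left* clip is
#' compared against the construct tail, mirrored.
#'
#' @param alignments SAM alignment data.frame (see [read_sam()]).
#' @param construct a [transposon_construct()].
#' @param min_clip_length minimum clipped-tail length considered.
#' @param min_identity minimum ungapped identity to a construct end.
#' @param host_contigs contigs treated as host; defaults to every contig
#'   other than the construct.
#' @return data.frame of evidence: `read_name`, `host_contig`,
#'   `junction_position` (1-based host coordinate of the terminal
#'   aligned base), `clip_side`, `clipped_sequence`,
#'   `matched_construct_end`, `orientation`, `match_identity`.
#' @export
extract_softclip_evidence <- function(alignments, construct,
                                      min_clip_length = 20L,
                                      min_identity = 0.9,
                                      host_contigs = NULL) {
  stopifnot(inherits(construct, "transposon_construct"))
  aln <- alignments
  if (is.null(host_contigs))
    host_contigs <- setdiff(unique(aln$rname), c(construct$name, "*"))
  keep <- bitwAnd(aln$flag, FLAG_UNMAPPED) == 0L &
    bitwAnd(aln$flag, FLAG_DUPLICATE) == 0L &
    aln$rname %in% host_contigs & aln$cigar != "*"
  aln <- aln[keep, , drop = FALSE]
  empty <- data.frame(read_name = character(0), host_contig = character(0),
                      junction_position = integer(0), clip_side = character(0),
                      clipped_sequence = character(0),
                      matched_construct_end = character(0),
                      orientation = character(0), match_identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(aln)) return(empty)
  clips <- cigar_clip_lengths(aln$cigar)
  refspan <- cigar_ref_span(aln$cigar)
  rc_full <- revcomp(construct$sequence)

  score_clip <- function(clip_seq, side) {
    ## best construct end for this clip.  A right clip reads outward
    ## into the start of the inserted block (construct prefix if
    ## forward, reverse-complement prefix if reverse); a left clip is
    ## the mirrored tail.
    if (side == "right") {
      cand <- rbind(
        left = c("forward",
                 ungapped_identity(clip_seq, construct$sequence,
                                   "start")["identity"]),
        right = c("reverse",
                  ungapped_identity(clip_seq, rc_full, "start")["identity"]))
    } else {
      cand <- rbind(
        right = c("forward",
                  ungapped_identity(clip_seq, construct$sequence,
                                    "end")["identity"]),
        left = c("reverse",
                 ungapped_identity(clip_seq, rc_full, "end")["identity"]))
    }
    ident <- as.numeric(cand[, 2])
    best <- which.max(ident)
    list(end = rownames(cand)[best], orientation = unname(cand[best, 1]),
         identity = ident[best])
  }

  out <- list()
  for (side in c("left", "right")) {
    len <- if (side == "left") clips$left else clips$right
    idx <- which(len >= min_clip_length)
    if (!length(idx)) next
    clip_seq <- if (side == "left") {
      substr(aln$seq[idx], 1L, len[idx])
    } else {
      substr(aln$seq[idx], nchar(aln$seq[idx]) - len[idx] + 1L,
             nchar(aln$seq[idx]))
    }
    junction <- if (side == "left") aln$pos[idx] else
      aln$pos[idx] + refspan[idx] - 1L
    hits <- lapply(clip_seq, score_clip, side = side)
    ident <- vapply(hits, `[[`, numeric(1), "identity")
    ok <- ident >= min_identity
    if (!any(ok)) next
    out[[side]] <- data.frame(
      read_name = aln$qname[idx][ok],
      host_contig = aln$rname[idx][ok],
      junction_position = junction[ok],
      clip_side = side,
      clipped_sequence = clip_seq[ok],
      matched_construct_end = vapply(hits[ok], `[[`, character(1), "end"),
      orientation = vapply(hits[ok], `[[`, character(1), "orientation"),
      match_identity = ident[ok],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$host_contig, ev$junction_position), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Cluster junction evidence into integration calls
#'
#' Evidence items within `cluster_window` bases on one contig are merged
#' into a candidate; candidates supported by at least `min_support`
#' reads become calls.  The TSD is located by an exact motif match in
#' the host sequence within one motif length of the junction cluster;
#' when found, the reported 1-based inclusive interval is the motif
#' occurrence, otherwise the clip consensus +/- 2 bp and an empty TSD
#' (real sites are not discarded over motif noise).  Orientation is the
#' majority vote of the per-read end assignments (construct left end at
#' a right clip = forward); conflicting clusters are flagged ambiguous.
#'
#' @param evidence data.frame from [extract_softclip_evidence()].
#' @param host_genome host reference (character vector / DNAStringSet /
#'   `synthetic_genome`).
#' @param tsd_motif duplication motif to search for ("TTAA" or "TA").
#' @param min_support minimum supporting reads per call.
#' @param cluster_window clustering distance in bases.
#' @return data.frame of calls: `host_contig`, `site_start`, `site_end`,
#'   `orientation`, `tsd_sequence`, `support_reads`, `ambiguous`,
#'   `five_prime_gene`, `three_prime_gene`, `genic`.
#' @export
cluster_and_call <- function(evidence, host_genome, tsd_motif = "TTAA",
                             min_support = 3L, cluster_window = 5L) {
  genome <- as_genome_chr(host_genome)
  empty <- data.frame(host_contig = character(0), site_start = integer(0),
                      site_end = integer(0), orientation = character(0),
                      tsd_sequence = character(0), support_reads = integer(0),
                      ambiguous = logical(0),
                      five_prime_gene = character(0),
                      three_prime_gene = character(0), genic = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(evidence) || !nrow(evidence)) return(empty)
  ev <- evidence[order(evidence$host_contig, evidence$junction_position), ,
                 drop = FALSE]
  new_cluster <- c(TRUE, ev$host_contig[-1] != ev$host_contig[-nrow(ev)] |
                     diff(ev$junction_position) > cluster_window)
  ev$cluster <- cumsum(new_cluster)
  m <- nchar(tsd_motif)
  calls <- lapply(split(ev, ev$cluster), function(cl) {
    support <- length(unique(cl$read_name))
    if (support < min_support) return(NULL)
    contig <- cl$host_contig[1]
    lo <- min(cl$junction_position); hi <- max(cl$junction_position)
    cons <- as.integer(round(median(cl$junction_position)))
    ## exact TSD motif within one motif length of the junction cluster
    s_lo <- max(1L, lo - m)
    s_hi <- min(nchar(genome[[contig]]), hi + m)
    region <- substr(genome[[contig]], s_lo, s_hi + m - 1L)
    occ <- gregexpr(tsd_motif, region, fixed = TRUE)[[1]]
    tab <- table(cl$orientation)
    orientation <- names(tab)[which.max(tab)]
    if (length(tab) > 1 && tab[orientation] == min(tab)) orientation <- "forward"
    ambiguous <- length(tab) > 1
    if (occ[1] != -1) {
      starts <- s_lo + as.integer(occ) - 1L
      best <- starts[which.min(abs(starts + (m - 1) / 2 - cons))]
      site_start <- best; site_end <- best + m - 1L
      tsd <- tsd_motif
    } else {
      site_start <- max(1L, cons - 2L); site_end <- cons + 2L
      tsd <- ""
    }
    data.frame(host_contig = contig, site_start = site_start,
               site_end = site_end, orientation = orientation,
               tsd_sequence = tsd, support_reads = support,
               ambiguous = ambiguous,
               five_prime_gene = NA_character_,
               three_prime_gene = NA_character_, genic = FALSE,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls)) return(empty)
  rownames(calls) <- NULL
  calls
}

#' Annotate integration calls with flanking genes
#'
#' Fills `five_prime_gene` (nearest gene ending at or before the site
#' start), `three_prime_gene` (nearest gene starting at or after the
#' site end) and the `genic` flag (site inside a gene span, which is
#' then reported on both sides).
#'
#' @param calls data.frame from [cluster_and_call()].
#' @param model a [gene_model()].
#' @return the calls with gene columns filled ("none" where no gene
#'   exists on that side).
#' @export
annotate_flanking_genes <- function(calls, model) {
  stopifnot(inherits(model, "gene_model"))
  if (!nrow(calls)) return(calls)
  g <- model$genes
  gct <- as.character(GenomicRanges::seqnames(g))
  for (i in seq_len(nrow(calls))) {
    on_ct <- which(gct == calls$host_contig[i])
    s <- calls$site_start[i]; e <- calls$site_end[i]
    inside <- on_ct[GenomicRanges::start(g)[on_ct] <= s &
                      GenomicRanges::end(g)[on_ct] >= e]
    if (length(inside)) {
      calls$five_prime_gene[i] <- g$gene_id[inside[1]]
      calls$three_prime_gene[i] <- g$gene_id[inside[1]]
      calls$genic[i] <- TRUE
      next
    }
    up <- on_ct[GenomicRanges::end(g)[on_ct] <= s]
    dn <- on_ct[GenomicRanges::start(g)[on_ct] >= e]
    calls$five_prime_gene[i] <- if (length(up))
      g$gene_id[up[which.max(GenomicRanges::end(g)[up])]] else "none"
    calls$three_prime_gene[i] <- if (length(dn))
      g$gene_id[dn[which.min(GenomicRanges::start(g)[dn])]] else "none"
  }
  calls
}

#' Assemble 5' junction sequences for verification
#'
#' For each call, concatenates the host flank upstream of the site, the
#' TSD, and the leading construct end in insertion orientation (reverse
#' calls use the reverse-complemented construct), the string a
#' primer-design check of the genome-to-transposon junction would use.
#'
#' @param calls data.frame of integration calls.
#' @param host_genome host reference.
#' @param construct a [transposon_construct()].
#' @param flank host bases upstream of the site to include.
#' @return character vector of junction strings, one per call.
#' @export
junction_report <- function(calls, host_genome, construct, flank = 50L) {
  genome <- as_genome_chr(host_genome)
  if (!nrow(calls)) return(character(0))
  vapply(seq_len(nrow(calls)), function(i) {
    ct <- calls$host_contig[i]
    s <- calls$site_start[i]
    f_lo <- s - flank
    if (f_lo < 1L) {
      warning("flank truncated at contig start for call ", i)
      f_lo <- 1L
    }
    flank_seq <- if (flank > 0) substr(genome[[ct]], f_lo, s - 1L) else ""
    tsd <- if (nzchar(calls$tsd_sequence[i])) calls$tsd_sequence[i] else
      substr(genome[[ct]], s, calls$site_end[i])
    end_seq <- if (calls$orientation[i] == "forward") construct$left_end
      else revcomp(construct$right_end)
    paste0(flank_seq, tsd, end_seq)
  }, character(1))
}

#' Run the full integration-calling stage
#'
#' Convenience wrapper: evidence extraction, clustering/calling and
#' flanking-gene annotation in one step.
#'
#' @param alignments SAM alignment data.frame.
#' @param host_genome host reference.
#' @param construct a [transposon_construct()].
#' @param model optional [gene_model()] for flanking-gene annotation.
#' @param min_clip_length,min_identity,min_support,cluster_window
#'   thresholds (see the stage functions).
#' @return data.frame of annotated integration calls.
#' @export
call_integrations <- function(alignments, host_genome, construct,
                              model = NULL, min_clip_length = 20L,
                              min_identity = 0.9, min_support = 3L,
                              cluster_window = 5L) {
  ev <- extract_softclip_evidence(alignments, construct,
                                  min_clip_length = min_clip_length,
                                  min_identity = min_identity)
  calls <- cluster_and_call(ev, host_genome,
                            tsd_motif = construct$tsd_motif,
                            min_support = min_support,
                            cluster_window = cluster_window)
  if (!is.null(model)) calls <- annotate_flanking_genes(calls, model)
  calls
}

#' Write integration calls as a report table
#'
#' Tab-separated table with 1-based inclusive coordinates (chromosome,
#' insertion site, orientation, TSD, support, flanking genes).
#'
#' @param calls data.frame of calls.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_integration_calls <- function(calls, path) {
  out <- calls[c("host_contig", "site_start", "site_end", "orientation",
                 "tsd_sequence", "support_reads", "five_prime_gene",
                 "three_prime_gene")]
  names(out)[1:3] <- c("chromosome", "insertion_site_start",
                       "insertion_site_end")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
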