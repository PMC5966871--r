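## Paired-end read simulator with a built-in "truth aligner": every read
## is sampled from the modified (insertion-bearing) genome, and its
## alignment against the unmodified host reference plus the construct
## contig is computed by a piecewise coordinate map rather than an
## external aligner.  Reads crossing an insertion junction receive soft
## clips exactly where a mapper would place them: the segment holding
## the majority of the read gets the match, the minority is clipped.

#' Simulate paired-end reads with ground-truth alignments
#'
#' Fragments of fixed length are drawn uniformly from each (modified)
#' contig; the two 150 bp ends are reported as sequenced (mate 2
#' reverse-complemented), with optional uniform substitution errors.
#' The expected pair count is `depth * genome_length / (2 * read_length)`.
#'
#' Truth alignments are expressed against the host reference plus one
#' contig for the construct.  Because the TSD motif is duplicated, the
#' host coordinates downstream of an insertion resume at the motif start
#' — precisely the double-counting a real aligner produces, which makes
#' left- and right-clip junction evidence bracket the TSD.
#'
#' @param genome a `planted_genome` (from [plant_insertions()]), a
#'   `synthetic_genome`, or a named character vector / DNAStringSet.
#' @param depth target haploid coverage.
#' @param read_length read length in bases.
#' @param fragment_length insert size (>= `read_length`).
#' @param error_rate per-base substitution probability.
#' @param duplicate_fraction fraction of pairs marked with the PCR
#'   duplicate flag (duplicates are extra copies of existing pairs).
#' @param seed RNG seed.
#' @return list with `reads` (data.frame: `name`, `sequence`, `quality`,
#'   `mate`), `truth` (alignment data.frame in SAM columns), and
#'   `header` (SAM header lines covering host + construct contigs).
#' @export
simulate_reads <- function(genome, depth = 30, read_length = 150L,
                           fragment_length = 350L, error_rate = 0,
                           duplicate_fraction = 0, seed = 1L) {
  stopifnot(fragment_length >= read_length, depth > 0)
  if (inherits(genome, "planted_genome")) {
    pg <- genome
  } else {
    ref <- if (inherits(genome, "synthetic_genome")) genome$genome else
      as_genome_chr(genome)
    pg <- list(reference = ref, modified = ref, construct = NULL,
               segments = lapply(nchar(ref), function(n)
                 build_segments(n, integer(0), character(0), 0L, 0L)))
  }
  rl <- as.integer(read_length)
  fl <- as.integer(fragment_length)
  if (any(nchar(pg$modified) < fl))
    stop("fragment length exceeds a contig length")
  cname <- if (!is.null(pg$construct)) pg$construct$name else NULL
  Lc <- if (!is.null(pg$construct)) nchar(pg$construct$sequence) else 0L

  withr::with_seed(seed, {
    per_contig <- lapply(names(pg$modified), function(ct) {
      s <- pg$modified[[ct]]
      n_pairs <- as.integer(round(depth * nchar(s) / (2 * rl)))
      if (n_pairs == 0) return(NULL)
      fs <- sample.int(nchar(s) - fl + 1L, n_pairs, replace = TRUE)
      fe <- fs + fl - 1L
      frag <- rep(seq_len(n_pairs), 2L)
      mate <- rep(c(1L, 2L), each = n_pairs)
      a <- c(fs, fe - rl + 1L)
      b <- a + rl - 1L
      ref_seq <- substring(s, a, b)
      segs <- pg$segments[[ct]]
      map <- map_spans(a, b, segs, ct, cname, Lc)
      data.frame(contig = ct, frag = frag, mate = mate, a = a, b = b,
                 ref_seq = ref_seq, rname = map$rname, pos = map$pos,
                 cigar = map$cigar, target_rev = map$target_rev,
                 stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, per_contig)
    if (is.null(rec)) stop("no reads simulated; increase depth or genome size")
    rec$name <- sprintf("%s_frag%07d", rec$contig, rec$frag)

    ## as-sequenced reads: mate 2 is the reverse complement
    seqd <- rec$ref_seq
    m2 <- rec$mate == 2L
    seqd[m2] <- revcomp(seqd[m2])
    ## substitution errors on the sequenced read
    if (error_rate > 0) {
      n_err <- rbinom(nrow(rec), rl, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(rl, n_err[i])
        ch <- strsplit(seqd[i], "")[[1]]
        ch[pos] <- vapply(ch[pos], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
        seqd[i] <- paste(ch, collapse = "")
      }
    }
    qual <- strrep("I", rl)
    reads <- data.frame(name = rec$name, sequence = seqd, quality = qual,
                        mate = rec$mate, stringsAsFactors = FALSE)

    ## truth SAM: stored sequence in target-reference orientation
    stored <- seqd
    stored[m2] <- revcomp(stored[m2])          # back to modified-genome strand
    tr <- rec$target_rev
    stored[tr] <- revcomp(stored[tr])          # construct hit on minus strand
    stored_rev <- xor(m2, tr)
    flag <- FLAG_PAIRED +
      ifelse(rec$mate == 1L, FLAG_FIRST, FLAG_SECOND) +
      ifelse(stored_rev, FLAG_REVERSE, 0L)
    truth <- data.frame(qname = rec$name, flag = as.integer(flag),
                        rname = rec$rname, pos = rec$pos, mapq = 60L,
                        cigar = rec$cigar, rnext = "*", pnext = 0L,
                        tlen = 0L, seq = stored, qual = qual,
                        stringsAsFactors = FALSE)
    if (duplicate_fraction > 0) {
      key <- paste(rec$contig, rec$frag)
      n_dup <- as.integer(round(duplicate_fraction * length(unique(key))))
      if (n_dup > 0) {
        dup_key <- sample(unique(key), n_dup)
        sel <- key %in% dup_key
        dup <- truth[sel, , drop = FALSE]
        dup$qname <- paste0(dup$qname, "_dup")
        dup$flag <- dup$flag + FLAG_DUPLICATE
        dreads <- reads[sel, , drop = FALSE]
        dreads$name <- paste0(dreads$name, "_dup")
        truth <- rbind(truth, dup)
        reads <- rbind(reads, dreads)
      }
    }
    hdr_genome <- pg$reference
    if (!is.null(pg$construct)) {
      hdr_genome <- c(hdr_genome, setNames(pg$construct$sequence, cname))
    }
    list(reads = reads, truth = truth, header = sam_header(hdr_genome))
  })
}

## Map modified-coordinate spans [a, b] to (rname, pos, cigar) on the
## host-or-construct target.  Vectorized fast path for reads contained
## in one segment; junction reads fall back to a per-read loop.
map_spans <- function(a, b, segs, contig, cname, Lc) {
  n <- length(a)
  ia <- findInterval(a, segs$mod_start)
  ib <- findInterval(b, segs$mod_start)
  rl <- b - a + 1L
  rname <- character(n); pos <- integer(n)
  cigar <- character(n); target_rev <- logical(n)

  same <- ia == ib
  if (any(same)) {
    si <- ia[same]
    host <- segs$type[si] == "host"
    rname[same] <- ifelse(host, contig, cname)
    full_m <- sprintf("%dM", rl[same])
    cigar[same] <- full_m
    pos_host <- a[same] - segs$offset[si]
    fwd <- !host & segs$orient[si] == "forward"
    rev <- !host & segs$orient[si] == "reverse"
    p <- integer(sum(same))
    p[host] <- pos_host[host]
    p[fwd] <- (a[same] - segs$block_start[si] + 1L)[fwd]
    p[rev] <- (Lc - (b[same] - segs$block_start[si]))[rev]
    pos[same] <- p
    target_rev[same] <- rev
  }
  for (i in which(!same)) {
    cand <- ia[i]:ib[i]
    ov <- pmin(b[i], segs$mod_end[cand]) - pmax(a[i], segs$mod_start[cand]) + 1L
    ## majority segment; ties favor the host side
    best <- cand[order(-ov, segs$type[cand] != "host")][1]
    ma <- max(a[i], segs$mod_start[best])
    mb <- min(b[i], segs$mod_end[best])
    lS <- ma - a[i]; rS <- b[i] - mb
    mlen <- mb - ma + 1L
    if (segs$type[best] == "host") {
      rname[i] <- contig
      pos[i] <- ma - segs$offset[best]
      cigar[i] <- cigar_string(lS, mlen, rS)
    } else if (segs$orient[best] == "forward") {
      rname[i] <- cname
      pos[i] <- ma - segs$block_start[best] + 1L
      cigar[i] <- cigar_string(lS, mlen, rS)
    } else {
      rname[i] <- cname
      pos[i] <- Lc - (mb - segs$block_start[best])
      cigar[i] <- cigar_string(rS, mlen, lS)  # clip sides swap on minus strand
      target_rev[i] <- TRUE
    }
  }
  list(rname = rname, pos = pos, cigar = cigar, target_rev = target_rev)
}

cigar_string <- function(left_s, m, right_s) {
  paste0(if (left_s > 0) sprintf("%dS", left_s) else "",
         sprintf("%dM", m),
         if (right_s > 0) sprintf("%dS", right_s) else "")
}
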