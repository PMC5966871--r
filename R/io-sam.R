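## Text SAM reader/writer.  The pipeline deliberately works on the
## plain-text SAM dialect (header @SQ lines plus the 11 mandatory
## columns); flag support is limited to the paired / strand / mate /
## duplicate bits, which is all the downstream counters consume.

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

FLAG_PAIRED    <- 0x1L
FLAG_REVERSE   <- 0x10L
FLAG_UNMAPPED  <- 0x4L
FLAG_FIRST     <- 0x40L
FLAG_SECOND    <- 0x80L
FLAG_DUPLICATE <- 0x400L

#' Build a minimal SAM header for a set of reference sequences
#'
#' @param genome named character vector or DNAStringSet of reference
#'   contigs (host genome, optionally with the construct contig appended).
#' @return character vector of header lines.
#' @export
sam_header <- function(genome) {
  g <- as_genome_chr(genome)
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(g), nchar(g)))
}

#' Parse CIGAR strings into operation tables
#'
#' @param cigar character vector of CIGAR strings (`*` allowed).
#' @return list of data.frames with columns `op` and `len`, one per input.
#' @export
parse_cigar <- function(cigar) {
  lapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*")
      return(data.frame(op = character(0), len = integer(0)))
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (sum(nchar(toks)) != nchar(cg)) stop("malformed CIGAR: ", cg)
    data.frame(op = substr(toks, nchar(toks), nchar(toks)),
               len = as.integer(substr(toks, 1, nchar(toks) - 1L)),
               stringsAsFactors = FALSE)
  })
}

## Vectorized CIGAR summaries used by the callers and window counters.
cigar_clip_lengths <- function(cigar) {
  has_left <- grepl("^[0-9]+S", cigar)
  left <- integer(length(cigar))
  left[has_left] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cigar[has_left]))
  ## right clip requires a preceding non-clip op so "150S" alone counts
  ## as a (degenerate) left clip only
  has_right <- grepl("[MIDNHP=X][0-9]+S$", cigar)
  right <- integer(length(cigar))
  right[has_right] <- as.integer(sub("^.*[MIDNHP=X]([0-9]+)S$", "\\1",
                                     cigar[has_right]))
  list(left = left, right = right)
}

## sum of operation lengths for a set of cigar ops, with a fast path
## for the ubiquitous all-match "<n>M" cigar
cigar_op_sum <- function(cigar, ops) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  if ("M" %in% ops)
    out[simple] <- as.integer(sub("M", "", cigar[simple], fixed = TRUE))
  rest <- which(!simple)
  if (length(rest)) {
    toks <- regmatches(cigar[rest], gregexpr("[0-9]+[MIDNSHP=X]", cigar[rest]))
    out[rest] <- vapply(toks, function(t) {
      op <- substr(t, nchar(t), nchar(t))
      sum(as.integer(substr(t, 1L, nchar(t) - 1L))[op %in% ops])
    }, integer(1))
  }
  out
}

## reference span consumed by a cigar (M/D/N/=/X)
cigar_ref_span <- function(cigar) {
  cigar_op_sum(cigar, c("M", "D", "N", "=", "X"))
}

## read length implied by a cigar (M/I/S/=/X)
cigar_read_len <- function(cigar) {
  cigar_op_sum(cigar, c("M", "I", "S", "=", "X"))
}

validate_sam <- function(aln) {
  has_seq <- !is.na(aln$seq) & aln$seq != "*"
  has_cig <- !is.na(aln$cigar) & aln$cigar != "*"
  idx <- which(has_seq & has_cig)
  if (length(idx)) {
    implied <- cigar_read_len(aln$cigar[idx])
    bad <- implied != nchar(aln$seq[idx])
    if (any(bad))
      stop(sprintf("CIGAR/sequence length mismatch for read '%s' (cigar %s, %d bases)",
                   aln$qname[idx][bad][1], aln$cigar[idx][bad][1],
                   nchar(aln$seq[idx])[bad][1]))
  }
  if (any(aln$pos < 0)) stop("negative SAM position")
  ## soft clips only at cigar ends
  inner <- grepl("[0-9]+S[0-9]", sub("^[0-9]+S", "", aln$cigar[has_cig]))
  inner <- inner & !grepl("S$", aln$cigar[has_cig])
  if (any(inner))
    stop("internal soft clip in CIGAR: ", aln$cigar[has_cig][inner][1])
  invisible(aln)
}

#' Read a text SAM file
#'
#' @param path SAM file.
#' @return list with `header` (character vector of `@` lines) and
#'   `alignments` (data.frame with the 11 mandatory SAM columns; `pos`
#'   keeps the SAM 1-based convention).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0) {
    aln <- as.data.frame(setNames(rep(list(character(0)), 11), SAM_COLS))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 11))
      stop(path, ": SAM record with fewer than 11 fields at body line ",
           which(nf < 11)[1])
    mat <- t(vapply(parts, function(p) p[1:11], character(11)))
    aln <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(aln) <- SAM_COLS
  }
  for (col in c("flag", "pos", "mapq", "pnext", "tlen"))
    aln[[col]] <- as.integer(aln[[col]])
  ## contigs referenced by records must be declared in the header
  sq <- sub("^.*SN:([^\t]+).*$", "\\1", hdr[startsWith(hdr, "@SQ")])
  mapped <- aln$rname != "*"
  if (any(mapped) && !all(aln$rname[mapped] %in% sq))
    stop(path, ": record references contig absent from header: ",
         setdiff(aln$rname[mapped], sq)[1])
  validate_sam(aln)
  list(header = hdr, alignments = aln)
}

#' Write alignments to a text SAM file
#'
#' @param alignments data.frame with the 11 mandatory SAM columns.
#' @param header character vector of header lines (see [sam_header()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, header, path) {
  validate_sam(alignments)
  body <- do.call(paste, c(alignments[SAM_COLS], sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
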