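## Reads are carried as a plain data.frame with columns
## name, sequence, quality (Phred+33 ASCII string), mate (1 or 2).
## This keeps per-base quality arithmetic (trimming) simple while FASTQ
## parsing/writing itself is delegated to Biostrings.

read_df <- function(name, sequence, quality, mate = 1L) {
  stopifnot(length(name) == length(sequence), length(sequence) == length(quality))
  if (any(nchar(sequence) != nchar(quality)))
    stop("sequence and quality lengths differ")
  data.frame(name = as.character(name), sequence = as.character(sequence),
             quality = as.character(quality), mate = as.integer(mate),
             stringsAsFactors = FALSE)
}

#' Convert a Phred+33 quality string to integer scores
#'
#' @param qual character vector of quality strings.
#' @return list of integer vectors (one per read).
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

phred_string <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (Phred+33).
#' @param mate mate index recorded for every read (1 or 2).
#' @return data.frame with columns `name`, `sequence`, `quality`, `mate`.
#' @export
read_fastq <- function(path, mate = 1L) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  read_df(names(x), as.character(x),
          as.character(S4Vectors::mcols(x)$qualities), mate)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame as returned by [read_fastq()] / [simulate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$name
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

## One trimming pass over a single quality vector; returns c(start, end)
## keep-range or c(0, -1) when the read should be dropped.
trim_range_once <- function(q, threshold, window) {
  L <- length(q)
  w <- as.integer(min(window, L))
  ## rolling window means
  cs <- cumsum(c(0, q))
  m <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  pass <- which(m >= threshold)
  if (length(pass) == 0) return(c(0L, -1L))
  s <- pass[1]
  while (s <= L && q[s] < threshold) s <- s + 1L
  e <- pass[length(pass)] + w - 1L
  while (e >= 1 && q[e] < threshold) e <- e - 1L
  if (s > e) return(c(0L, -1L))
  c(s, e)
}

## Iterate the windowed trim to a fixpoint so trimming is idempotent.
trim_range <- function(q, threshold, window) {
  s0 <- 1L; e0 <- length(q)
  repeat {
    r <- trim_range_once(q[s0:e0], threshold, window)
    if (r[2] < r[1]) return(c(0L, -1L))
    s1 <- as.integer(s0 + r[1] - 1L); e1 <- as.integer(s0 + r[2] - 1L)
    if (s1 == s0 && e1 == e0) return(c(s0, e0))
    s0 <- s1; e0 <- e1
  }
}

#' Quality-trim reads with a sliding window
#'
#' Windowed quality trimming in the style of classic read cleaners: a
#' window (default 10 bases) slides in from each end and the read is cut
#' where mean window quality first reaches the threshold; sub-threshold
#' bases at the cut edge are then stripped, and the procedure is iterated
#' to a fixpoint so that trimming twice equals trimming once.  Reads
#' shorter than `min_length` after trimming are dropped.  A read is never
#' lengthened.
#'
#' @param reads data.frame with `name`, `sequence`, `quality`, `mate`.
#' @param phred_threshold minimum acceptable mean window quality
#'   (default 20, i.e. 1% error).
#' @param window sliding-window width in bases.
#' @param min_length minimum surviving read length.
#' @return data.frame of surviving (possibly shortened) reads.
#' @export
trim_reads <- function(reads, phred_threshold = 20L, window = 10L,
                       min_length = 50L) {
  stopifnot(phred_threshold >= 0)
  if (nrow(reads) == 0) return(reads)
  scores <- phred_scores(reads$quality)
  rng <- vapply(scores, trim_range, integer(2),
                threshold = phred_threshold, window = window)
  keep <- rng[2, ] - rng[1, ] + 1L >= min_length
  out <- reads[keep, , drop = FALSE]
  if (nrow(out)) {
    out$sequence <- substr(out$sequence, rng[1, keep], rng[2, keep])
    out$quality  <- substr(out$quality,  rng[1, keep], rng[2, keep])
  }
  rownames(out) <- NULL
  out
}
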