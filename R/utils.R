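#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rbinom rnorm rpois runif setNames complete.cases
#' @importFrom utils read.delim write.table head tail packageVersion
#' @importFrom methods is
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

## Coerce a genome given as DNAStringSet or character vector to a named
## uppercase character vector (the simulators do heavy string surgery,
## which is simplest on plain character).
as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else if (is.list(genome) && !is.null(genome$genome)) {
    return(as_genome_chr(genome$genome))
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyDuplicated(names(out)) || any(names(out) == ""))
    stop("genome contigs must have unique non-empty names")
  out
}

as_dna_stringset <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(as_genome_chr(genome))
}

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a reproducible stage-specific seed
#'
#' Fans one global seed out to per-stage seeds so stages can be rerun
#' independently yet reproducibly; results stay within 32-bit integer
#' range.
#'
#' @param seed global integer seed.
#' @param stage stage label (any string).
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 7919) %% (.Machine$integer.max - 1L)) + 1L
}

check_alphabet <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(sprintf("%s contains characters outside ACGTN (first offender: record %d)",
                 what, which(bad)[1]))
  invisible(TRUE)
}

## GC fraction of character sequences (N excluded from denominator).
gc_fraction <- function(seqs) {
  s <- Biostrings::DNAStringSet(seqs)
  gc <- Biostrings::letterFrequency(s, letters = "GC")[, 1]
  acgt <- Biostrings::letterFrequency(s, letters = "ACGT")[, 1]
  ifelse(acgt > 0, gc / acgt, NA_real_)
}
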