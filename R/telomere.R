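## Telomere length from the frequency of telomere-repeat-rich reads.
## A read is telomeric when it carries at least k non-overlapping copies
## of TTAGGG (or its reverse complement CCCTAA); the genome-wide
## fraction of such reads, scaled by genome length and the number of
## chromosome ends, estimates the mean per-end tract length.

#' Estimate telomere length from read frequency
#'
#' `estimated_length_kb = telomeric_reads * genome_length /
#' (total_reads * n_chromosome_ends * 1000)` — the abundance estimator
#' behind read-frequency telomere callers, without GC stratification.
#' Because it is fraction-based, the estimate is invariant to total
#' sequencing depth.
#'
#' @param reads character vector of read sequences, or a read
#'   data.frame with a `sequence` column (e.g. from [simulate_reads()]).
#' @param genome_length total reference length in bases.
#' @param n_chromosome_ends number of chromosome ends covered by the
#'   reads (2 per linear chromosome).
#' @param repeat_threshold_k minimum TTAGGG copies per telomeric read
#'   (default 7, the conventional threshold for 100 bp+ reads).
#' @return list of class `telomere_estimate`: `telomeric_read_count`,
#'   `total_read_count`, `estimated_length_kb`, `repeat_threshold_k`.
#' @export
estimate_telomere_length <- function(reads, genome_length,
                                     n_chromosome_ends,
                                     repeat_threshold_k = 7L) {
  if (n_chromosome_ends <= 0) stop("n_chromosome_ends must be positive")
  if (is.data.frame(reads)) reads <- reads$sequence
  total <- length(reads)
  if (total == 0) stop("no reads supplied")
  seqs <- Biostrings::DNAStringSet(reads)
  ## TTAGGG cannot overlap itself, so pattern counts are the
  ## non-overlapping copy numbers
  fwd <- Biostrings::vcountPattern(TELOMERE_MOTIF, seqs)
  rev <- Biostrings::vcountPattern(revcomp(TELOMERE_MOTIF), seqs)
  telomeric <- sum(fwd >= repeat_threshold_k | rev >= repeat_threshold_k)
  est <- as.numeric(telomeric) * as.numeric(genome_length) /
    (as.numeric(total) * n_chromosome_ends * 1000)
  structure(list(telomeric_read_count = as.integer(telomeric),
                 total_read_count = as.integer(total),
                 estimated_length_kb = est,
                 repeat_threshold_k = as.integer(repeat_threshold_k)),
            class = "telomere_estimate")
}

#' @export
print.telomere_estimate <- function(x, ...) {
  cat(sprintf(
    "<telomere_estimate> %.2f kb per end (%d / %d reads telomeric, k = %d)\n",
    x$estimated_length_kb, x$telomeric_read_count, x$total_read_count,
    x$repeat_threshold_k))
  invisible(x)
}
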