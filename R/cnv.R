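## Windowed, GC-normalized read-depth copy-number scan.  Reads are
## binned by leftmost mapped base into fixed-width windows, counts are
## rescaled by the median count of each window's GC bin (2% bins), and
## copy number is the normalized count relative to the autosomal median
## scaled to the diploid baseline of two.

#' Count reads per genomic window
#'
#' Each mapped, non-duplicate read on a host contig is assigned to the
#' window containing its leftmost mapped base.  GC fraction is computed
#' from the reference window sequence.
#'
#' @param alignments SAM alignment data.frame (see [read_sam()]).
#' @param genome host reference (character vector / DNAStringSet /
#'   `synthetic_genome`).
#' @param window_size window width in bases (> 0; terminal windows may
#'   be shorter).
#' @return data.frame of windows: `contig`, `start`, `end` (1-based
#'   inclusive), `gc_fraction`, `raw_count`.
#' @export
window_counts <- function(alignments, genome, window_size = 50000L) {
  stopifnot(window_size > 0)
  g <- as_genome_chr(genome)
  wins <- do.call(rbind, lapply(names(g), function(ct) {
    len <- nchar(g[[ct]])
    starts <- seq(1L, len, by = window_size)
    data.frame(contig = ct, start = starts,
               end = pmin(starts + window_size - 1L, len),
               stringsAsFactors = FALSE)
  }))
  wins$gc_fraction <- gc_fraction(substring(g[wins$contig], wins$start,
                                            wins$end))
  aln <- alignments
  keep <- bitwAnd(aln$flag, FLAG_UNMAPPED) == 0L &
    bitwAnd(aln$flag, FLAG_DUPLICATE) == 0L &
    aln$rname %in% names(g)
  aln <- aln[keep, , drop = FALSE]
  wins$raw_count <- 0L
  if (nrow(aln)) {
    widx <- match(
      paste(aln$rname, (aln$pos - 1L) %/% window_size, sep = ":"),
      paste(wins$contig, (wins$start - 1L) %/% window_size, sep = ":"))
    tab <- table(widx)
    wins$raw_count[as.integer(names(tab))] <- as.integer(tab)
  }
  wins
}

#' GC-normalize window counts
#'
#' Median-ratio normalization: windows are binned by GC fraction
#' (default 2% bins) and each raw count is scaled by
#' `global median / bin median`; bins with a zero or undefined median
#' fall back to the global median (scale 1).  A transparent stand-in
#' for black-box GC correction in dedicated CNV callers.
#'
#' @param windows data.frame from [window_counts()] (at least 20
#'   windows recommended for stable bin medians).
#' @param gc_bin_width GC bin width (fraction).
#' @return the windows with a `normalized_count` column.
#' @export
gc_normalize <- function(windows, gc_bin_width = 0.02) {
  if (all(windows$raw_count == 0))
    stop("all window counts are zero; nothing to normalize")
  if (nrow(windows) < 2) {
    windows$normalized_count <- as.numeric(windows$raw_count)
    return(windows)
  }
  global_med <- median(windows$raw_count)
  bin <- floor(windows$gc_fraction / gc_bin_width)
  bin_med <- tapply(windows$raw_count, bin, median)
  scale <- global_med / bin_med[as.character(bin)]
  scale[!is.finite(scale)] <- 1
  windows$normalized_count <- as.numeric(windows$raw_count) * as.numeric(scale)
  windows
}

#' Convert normalized counts to copy numbers
#'
#' `copy_number = 2 * normalized_count / median(normalized_count)` over
#' autosomal windows — the diploid baseline of two.
#'
#' @param windows data.frame with `normalized_count`.
#' @param autosomes contigs regarded as autosomal for the baseline
#'   median (default: all).
#' @return the windows with a `copy_number` column.
#' @export
copy_number <- function(windows, autosomes = NULL) {
  if (is.null(windows$normalized_count))
    stop("run gc_normalize() first")
  base <- if (is.null(autosomes)) windows else
    windows[windows$contig %in% autosomes, , drop = FALSE]
  med <- median(base$normalized_count)
  if (!is.finite(med) || med == 0) stop("zero median normalized count")
  windows$copy_number <- 2 * windows$normalized_count / med
  windows
}

#' Call copy-number gains and losses
#'
#' Windows above `high` are gains, below `low` losses; adjacent windows
#' of the same state on one contig are merged into interval calls.
#'
#' @param windows data.frame with `copy_number`.
#' @param low,high loss / gain thresholds (defaults 1.5 and 2.5 around
#'   the diploid value of two).
#' @return data.frame of calls: `contig`, `start`, `end`, `state`,
#'   `mean_copy_number`, `n_windows`.
#' @export
call_gain_loss <- function(windows, low = 1.5, high = 2.5) {
  if (is.null(windows$copy_number)) stop("run copy_number() first")
  state <- ifelse(windows$copy_number > high, "gain",
           ifelse(windows$copy_number < low, "loss", "neutral"))
  runs <- rle(paste(windows$contig, state, sep = ":"))
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  keep <- state[idx_start] != "neutral"
  if (!any(keep))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), state = character(0),
                      mean_copy_number = numeric(0), n_windows = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(which(keep), function(i) {
    rows <- idx_start[i]:idx_end[i]
    data.frame(contig = windows$contig[rows[1]],
               start = windows$start[rows[1]],
               end = windows$end[rows[length(rows)]],
               state = state[rows[1]],
               mean_copy_number = mean(windows$copy_number[rows]),
               n_windows = length(rows),
               stringsAsFactors = FALSE)
  }))
}
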