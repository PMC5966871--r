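#' Define a transposon construct
#'
#' Describes the integrated cargo: the full vector sequence, the two
#' terminal end sequences used to recognize junction-spanning reads
#' (inverted-terminal-repeat surrogates, at least 30 bases each), the
#' target-site-duplication motif of the transposase ("TTAA" for piggyBac,
#' "TA" for Sleeping Beauty), and named payload features (rox sites,
#' fluorophore ORFs, ...) as sub-intervals of the sequence.
#'
#' @param name construct name (also the contig name in truth alignments).
#' @param sequence full construct sequence (A/C/G/T/N).
#' @param tsd_motif `"TTAA"` or `"TA"`.
#' @param end_length length of the terminal end sequences (>= 30).
#' @param features data.frame with columns `name`, `start`, `end`
#'   (1-based inclusive) and optionally `strand`; may be empty.
#' @return an object of class `transposon_construct`.
#' @export
transposon_construct <- function(name, sequence, tsd_motif = c("TTAA", "TA"),
                                 end_length = 60L, features = NULL) {
  tsd_motif <- match.arg(tsd_motif)
  sequence <- toupper(sequence)
  check_alphabet(sequence, "construct sequence")
  if (end_length < 30L) stop("end sequences must be at least 30 bases")
  if (nchar(sequence) < 2 * end_length)
    stop("construct shorter than twice the end length")
  if (is.null(features))
    features <- data.frame(name = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           stringsAsFactors = FALSE)
  if (is.null(features$strand)) features$strand <- rep("+", nrow(features))
  if (nrow(features)) {
    if (any(features$start < 1 | features$end > nchar(sequence) |
            features$start > features$end))
      stop("payload feature outside construct bounds")
    o <- order(features$start)
    features <- features[o, , drop = FALSE]
    if (nrow(features) > 1 &&
        any(features$start[-1] <= features$end[-nrow(features)]))
      stop("payload features overlap")
    rownames(features) <- NULL
  }
  structure(list(
    name = name,
    sequence = sequence,
    left_end = substr(sequence, 1L, end_length),
    right_end = substr(sequence, nchar(sequence) - end_length + 1L,
                       nchar(sequence)),
    tsd_motif = tsd_motif,
    features = features
  ), class = "transposon_construct")
}

#' @export
print.transposon_construct <- function(x, ...) {
  cat(sprintf("<transposon_construct> %s: %d bp, TSD motif %s, %d feature(s)\n",
              x$name, nchar(x$sequence), x$tsd_motif, nrow(x$features)))
  if (nrow(x$features))
    cat(paste(sprintf("  %-10s %6d-%6d (%s)", x$features$name,
                      x$features$start, x$features$end, x$features$strand),
              collapse = "\n"), "\n")
  invisible(x)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Example piggyBac reporter construct
#'
#' A deterministic stand-in for a piggyBac vector carrying a rox-flanked
#' GFP cassette followed by RFP (rox-GFP-rox-RFP), with 60 bp terminal
#' end sequences and the TTAA duplication motif.  The sequence is
#' pseudo-random but fixed, not a real vector map.
#'
#' @param end_length terminal end-sequence length.
#' @return a [transposon_construct()].
#' @export
pb_example_construct <- function(end_length = 60L) {
  withr::with_seed(104729L, {
    rox <- random_dna(32)
    parts <- c(left  = random_dna(end_length),
               rox1  = rox,
               GFP   = random_dna(720),
               rox2  = rox,
               RFP   = random_dna(678),
               right = random_dna(end_length))
    ends <- cumsum(nchar(parts))
    starts <- ends - nchar(parts) + 1L
    feat <- data.frame(
      name = c("rox1", "GFP", "rox2", "RFP"),
      start = starts[c("rox1", "GFP", "rox2", "RFP")],
      end = ends[c("rox1", "GFP", "rox2", "RFP")],
      strand = "+", stringsAsFactors = FALSE)
    transposon_construct("PB_construct", paste(parts, collapse = ""),
                         tsd_motif = "TTAA", end_length = end_length,
                         features = feat)
  })
}

#' Example Sleeping Beauty reporter construct
#'
#' Deterministic pseudo-random Sleeping Beauty-style cargo (YFP payload)
#' with the TA duplication motif.
#'
#' @param end_length terminal end-sequence length.
#' @return a [transposon_construct()].
#' @export
sb_example_construct <- function(end_length = 60L) {
  withr::with_seed(130003L, {
    parts <- c(left = random_dna(end_length), YFP = random_dna(717),
               right = random_dna(end_length))
    feat <- data.frame(name = "YFP", start = end_length + 1L,
                       end = end_length + 717L, strand = "+",
                       stringsAsFactors = FALSE)
    transposon_construct("SB_construct", paste(parts, collapse = ""),
                         tsd_motif = "TA", end_length = end_length,
                         features = feat)
  })
}

#' Apply Dre-rox recombination to a construct
#'
#' Dre recombinase resolves two same-orientation rox sites into one,
#' excising the intervening cassette: a rox-GFP-rox-RFP construct
#' becomes rox-RFP.  The first same-orientation pair of features whose
#' names start with "rox" is recombined; the sequence from the start of
#' the first rox up to (but excluding) the start of the second rox is
#' removed, so exactly one rox copy remains and downstream features are
#' shifted left by the excised length.  With fewer than two rox sites
#' the construct is returned unchanged with a warning.
#'
#' @param construct a [transposon_construct()].
#' @return the recombined `transposon_construct`.
#' @export
apply_dre_recombination <- function(construct) {
  stopifnot(inherits(construct, "transposon_construct"))
  feat <- construct$features
  rox <- which(grepl("^rox", feat$name, ignore.case = TRUE))
  if (length(rox) >= 2) {
    ## first same-orientation pair
    pair <- NULL
    for (i in seq_along(rox)[-length(rox)]) {
      j <- which(feat$strand[rox] == feat$strand[rox[i]] & seq_along(rox) > i)[1]
      if (!is.na(j)) { pair <- c(rox[i], rox[j]); break }
    }
    if (is.null(pair)) {
      warning("no same-orientation rox pair; construct unchanged")
      return(construct)
    }
    a <- feat$start[pair[1]]; b <- feat$start[pair[2]]
    excised <- b - a
    seq2 <- paste0(substr(construct$sequence, 1L, a - 1L),
                   substr(construct$sequence, b, nchar(construct$sequence)))
    keep <- feat$start < a | feat$start >= b
    feat2 <- feat[keep, , drop = FALSE]
    shift <- feat2$start >= b
    feat2$start[shift] <- feat2$start[shift] - excised
    feat2$end[shift] <- feat2$end[shift] - excised
    ## the surviving copy is the single recombined rox site
    feat2$name[feat2$start == a & grepl("^rox", feat2$name,
                                        ignore.case = TRUE)] <- "rox"
    rownames(feat2) <- NULL
    out <- transposon_construct(construct$name, seq2,
                                tsd_motif = construct$tsd_motif,
                                end_length = nchar(construct$left_end),
                                features = feat2)
    attr(out, "excised_length") <- excised
    return(out)
  }
  warning("fewer than two rox sites; construct unchanged")
  construct
}
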