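#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased on read and the alphabet is restricted to
#' A/C/G/T/N; anything else is rejected with the offending line number,
#' so downstream exact-string matching (TSD motifs, construct ends,
#' telomere repeats) is deterministic.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] with unique names.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) return(Biostrings::DNAStringSet())
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) return(Biostrings::DNAStringSet())
  if (!startsWith(lines[nonempty[1]], ">"))
    stop(sprintf("%s: malformed FASTA header at line %d", path, nonempty[1]))
  seq_lines <- !startsWith(lines, ">") & nzchar(trimws(lines))
  bad <- which(seq_lines & grepl("[^ACGTNacgtn]", lines))
  if (length(bad))
    stop(sprintf("%s: illegal sequence character at line %d", path, bad[1]))
  x <- Biostrings::readDNAStringSet(path)
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  ## keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(Biostrings::width(x) == 0))
    stop(path, ": empty sequence record '", names(x)[Biostrings::width(x) == 0][1], "'")
  if (anyDuplicated(names(x)))
    stop(path, ": duplicate record name '", names(x)[duplicated(names(x))][1], "'")
  x
}

#' Write sequences to a FASTA file
#'
#' @param records a named character vector or [Biostrings::DNAStringSet].
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  x <- as_dna_stringset(records)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}
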