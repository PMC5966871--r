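## Trio genotype classification by allele-depth ratio and de novo
## mutation search.  Classification bands (strict inequalities, literal
## reading of the stated criteria):
##   RefHom  : ref / (ref + alt) > 0.90
##   Hetero  : 0.40 < ref / (ref + alt) < 0.60
##   AltHom  : alt / (ref + alt) > 0.90
## everything else, including ratios exactly at a boundary, is
## Ambiguous.  Ratios use the biallelic denominator ref + alt.

GENOTYPE_LEVELS <- c("RefHom", "Hetero", "AltHom", "Ambiguous")

#' Classify genotypes by allele-depth ratio
#'
#' @param ref_depth,alt_depth non-negative integer vectors of reference
#'   and alternate allele depths (total depth must be positive; filter
#'   zero-depth sites first).
#' @return factor with levels RefHom, Hetero, AltHom, Ambiguous.
#' @export
classify_genotype <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0 | alt_depth < 0)) stop("negative allele depth")
  total <- ref_depth + alt_depth
  if (any(total == 0)) stop("zero total depth; filter such sites first")
  r <- ref_depth / total
  a <- alt_depth / total
  out <- rep("Ambiguous", length(total))
  out[r > 0.90] <- "RefHom"
  out[r > 0.40 & r < 0.60] <- "Hetero"
  out[a > 0.90] <- "AltHom"
  factor(out, levels = GENOTYPE_LEVELS)
}

## expand an exclusion set: entries ending in "*" are prefix wildcards
contig_excluded <- function(contigs, excluded) {
  contigs <- as.character(contigs)
  if (!length(excluded)) return(rep(FALSE, length(contigs)))
  exact <- excluded[!endsWith(excluded, "*")]
  pref <- sub("\\*$", "", excluded[endsWith(excluded, "*")])
  hit <- contigs %in% exact
  for (p in pref) hit <- hit | startsWith(contigs, p)
  hit
}

#' Filter trio sites by genotype quality and contig exclusions
#'
#' Retains sites whose genotype quality is at least `min_genotype_quality`
#' in all three samples (sites lacking quality columns pass) and whose
#' contig is not excluded.  Exclusion entries ending in `*` are prefix
#' wildcards (e.g. `"unplaced*"`); the defaults drop the X chromosome,
#' the mitochondrial genome and unanchored scaffolds.
#'
#' @param records trio site data.frame (see [read_trio_table()]).
#' @param min_genotype_quality quality cutoff (default 60).
#' @param excluded_contigs character vector of exclusions.
#' @return the filtered data.frame.
#' @export
filter_sites <- function(records, min_genotype_quality = 60L,
                         excluded_contigs = c("X", "MT", "unplaced*")) {
  keep <- !contig_excluded(records$contig, excluded_contigs)
  gq_cols <- intersect(c("gq_sire", "gq_dam", "gq_off"), names(records))
  for (col in gq_cols) {
    v <- records[[col]]
    keep <- keep & (is.na(v) | v >= min_genotype_quality)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call de novo mutations in a trio
#'
#' A site is a de novo call iff both parents classify RefHom and the
#' offspring classifies Hetero (heterozygous de novo) or AltHom
#' (homozygous de novo).  An Ambiguous classification in any trio
#' member suppresses the call — remaining variants are searched as de
#' novo rather than imputed.
#'
#' @param records filtered trio site data.frame.
#' @return data.frame of calls: the site columns plus `offspring_class`
#'   (`"Hetero"`/`"AltHom"`), `positional_class` (NA until
#'   [annotate_position()]) and `repeat_artifact` (FALSE until
#'   [flag_repeat_artifacts()]).
#' @export
call_denovo <- function(records) {
  keep_cols <- c("contig", "pos", "ref", "alt", "sire_ref", "sire_alt",
                 "dam_ref", "dam_alt", "off_ref", "off_alt")
  if (!nrow(records)) {
    out <- records[intersect(keep_cols, names(records))]
    out$offspring_class <- character(0)
    out$positional_class <- character(0)
    out$repeat_artifact <- logical(0)
    return(out)
  }
  sire <- classify_genotype(records$sire_ref, records$sire_alt)
  dam <- classify_genotype(records$dam_ref, records$dam_alt)
  off <- classify_genotype(records$off_ref, records$off_alt)
  hit <- sire == "RefHom" & dam == "RefHom" & off %in% c("Hetero", "AltHom")
  out <- records[hit, intersect(keep_cols, names(records)), drop = FALSE]
  out$offspring_class <- as.character(off[hit])
  out$positional_class <- rep(NA_character_, nrow(out))
  out$repeat_artifact <- rep(FALSE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Flag de novo calls inside repeat intervals
#'
#' Homozygous "de novo" variants landing in long-terminal-repeat regions
#' are characteristic mapping artifacts; this marks any call whose
#' position lies within a repeat interval.
#'
#' @param calls data.frame from [call_denovo()].
#' @param repeat_intervals GRanges of repeat annotation (e.g. from
#'   [read_bed()]).
#' @return the calls with `repeat_artifact` set.
#' @export
flag_repeat_artifacts <- function(calls, repeat_intervals) {
  if (!nrow(calls)) return(calls)
  if (is.null(repeat_intervals) || length(repeat_intervals) == 0) {
    calls$repeat_artifact <- FALSE
    return(calls)
  }
  sites <- GenomicRanges::GRanges(calls$contig,
                                  IRanges::IRanges(calls$pos, calls$pos))
  hits <- IRanges::overlapsAny(sites, repeat_intervals,
                                     ignore.strand = TRUE)
  calls$repeat_artifact <- as.logical(hits)
  calls
}

#' Annotate de novo calls with positional classes
#'
#' Assigns `exonic` (inside any exon), else `intronic` (inside any gene
#' span), else `intergenic` — precedence exonic > intronic > intergenic.
#'
#' @param calls data.frame from [call_denovo()].
#' @param model a [gene_model()].
#' @return the calls with `positional_class` filled.
#' @export
annotate_position <- function(calls, model) {
  stopifnot(inherits(model, "gene_model"))
  if (!nrow(calls)) return(calls)
  sites <- GenomicRanges::GRanges(calls$contig,
                                  IRanges::IRanges(calls$pos, calls$pos))
  in_exon <- IRanges::overlapsAny(sites, model$exons,
                                        ignore.strand = TRUE)
  in_gene <- IRanges::overlapsAny(sites, model$genes,
                                        ignore.strand = TRUE)
  calls$positional_class <- ifelse(in_exon, "exonic",
                            ifelse(in_gene, "intronic", "intergenic"))
  calls
}

#' Per-generation mutation rate
#'
#' The number of de novo mutations divided by the number of callable
#' positions, i.e. the rate per position per generation.
#'
#' @param n_denovo de novo mutation count.
#' @param callable_positions denominator (> 0); e.g. the summed length
#'   of the included contigs.
#' @return the rate (numeric scalar).
#' @export
mutation_rate <- function(n_denovo, callable_positions) {
  if (callable_positions <= 0) stop("callable_positions must be positive")
  if (n_denovo < 0) stop("n_denovo must be non-negative")
  n_denovo / callable_positions
}

#' Summarize de novo calls (counts by class and position)
#'
#' @param calls annotated calls.
#' @return list with `n_het`, `n_hom`, `n_artifact`, and the positional
#'   breakdown of heterozygous calls.
#' @export
summarize_denovo <- function(calls) {
  het <- calls[calls$offspring_class == "Hetero", , drop = FALSE]
  pos <- table(factor(het$positional_class,
                      levels = c("intergenic", "intronic", "exonic")))
  list(n_het = nrow(het),
       n_hom = sum(calls$offspring_class == "AltHom"),
       n_artifact = sum(calls$repeat_artifact),
       positional = as.list(as.integer(pos) |>
                              setNames(names(pos))))
}

#' Read trio allele depths from a minimal VCF
#'
#' Accepts a plain-text VCF with per-sample `AD` (ref,alt depths) and
#' optional `GQ` fields for exactly three samples, in sire, dam,
#' offspring order (override with `samples`).  Multi-allelic records are
#' dropped with a message.
#'
#' @param path VCF file.
#' @param samples optional 3-vector of sample names (sire, dam,
#'   offspring).
#' @return trio site data.frame (layout of [read_trio_table()]).
#' @export
read_trio_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    message("dropping ", sum(multi), " multi-allelic record(s)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  ad <- vcfR::extract.gt(v, "AD")
  gq <- tryCatch(vcfR::extract.gt(v, "GQ", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(samples)) samples <- colnames(ad)[1:3]
  if (length(samples) != 3 || !all(samples %in% colnames(ad)))
    stop("three samples (sire, dam, offspring) required")
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = vapply(parts, function(p) as.integer(p[1]), integer(1)),
         alt = vapply(parts, function(p) as.integer(p[2]), integer(1)))
  }
  s <- split_ad(ad[, samples[1]])
  d <- split_ad(ad[, samples[2]])
  o <- split_ad(ad[, samples[3]])
  tab <- data.frame(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    sire_ref = s$ref, sire_alt = s$alt,
    dam_ref = d$ref, dam_alt = d$alt,
    off_ref = o$ref, off_alt = o$alt,
    stringsAsFactors = FALSE)
  if (!is.null(gq)) {
    tab$gq_sire <- gq[, samples[1]]
    tab$gq_dam <- gq[, samples[2]]
    tab$gq_off <- gq[, samples[3]]
  }
  tab
}
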