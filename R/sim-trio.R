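## Simulated trio (sire, dam, offspring) allele-depth tables with known
## truth labels, the input to the de novo classifier.  Per-site depth is
## Poisson around the configured mean; heterozygous alternate depths are
## binomial around 0.5, conditioned on the 40-60% band the depth-ratio
## classifier defines (a planted het represents a variant that satisfies
## the classification criteria, mirroring that reported de novo counts
## are themselves post-classification counts); homozygous-alternate
## sites keep alternate fractions above 95% before sequencing error.

#' Configuration for the trio depth simulator
#'
#' @param n_sites total number of sites in the table.
#' @param depth_mean mean per-sample depth (Poisson).
#' @param n_inherited_het sites heterozygous in the offspring and in
#'   exactly one parent (inherited, must not be called de novo).
#' @param n_denovo_het heterozygous de novo sites: a single count, or a
#'   named vector `c(intergenic=, intronic=, exonic=)` to control the
#'   positional class of the planted sites.
#' @param n_denovo_hom homozygous-alternate de novo sites placed outside
#'   repeat intervals.
#' @param n_artifact_hom_in_repeats homozygous-alternate de novo sites
#'   placed *inside* annotated LTR repeat intervals (the artifact class).
#' @param error_rate per-base sequencing error rate.
#' @param seed RNG seed.
#' @return a `trio_sim_config` list.
#' @export
trio_sim_config <- function(n_sites = 10000L, depth_mean = 30,
                            n_inherited_het = 0L, n_denovo_het = 0L,
                            n_denovo_hom = 0L,
                            n_artifact_hom_in_repeats = 0L,
                            error_rate = 0, seed = 1L) {
  stopifnot(depth_mean > 0, n_sites > 0, error_rate >= 0, error_rate < 0.5)
  counts <- c(n_inherited_het, sum(n_denovo_het), n_denovo_hom,
              n_artifact_hom_in_repeats)
  if (any(counts < 0)) stop("planted counts must be non-negative")
  if (sum(counts) > n_sites)
    stop("planted counts exceed n_sites")
  structure(list(n_sites = as.integer(n_sites), depth_mean = depth_mean,
                 n_inherited_het = as.integer(n_inherited_het),
                 n_denovo_het = n_denovo_het,
                 n_denovo_hom = as.integer(n_denovo_hom),
                 n_artifact_hom_in_repeats =
                   as.integer(n_artifact_hom_in_repeats),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "trio_sim_config")
}

## alt depths for het sites: Binomial(depth, 0.5) conditioned on the
## open 40-60% band (vectorized rejection)
rbinom_het_band <- function(depth) {
  alt <- rbinom(length(depth), depth, 0.5)
  bad <- which(alt / depth <= 0.40 | alt / depth >= 0.60)
  guard <- 0L
  while (length(bad)) {
    alt[bad] <- rbinom(length(bad), depth[bad], 0.5)
    bad <- bad[alt[bad] / depth[bad] <= 0.40 | alt[bad] / depth[bad] >= 0.60]
    guard <- guard + 1L
    if (guard > 10000L) stop("cannot satisfy het band; depth too low")
  }
  alt
}

## depths for a homozygous-reference sample: error-driven alternate
## reads, conditioned below the 10% noise level so a true RefHom sample
## stays inside its classification band
hom_ref_depths <- function(depth, error_rate) {
  if (error_rate == 0) return(cbind(ref = depth, alt = integer(length(depth))))
  alt <- rbinom(length(depth), depth, error_rate)
  bad <- which(alt / depth >= 0.10)
  guard <- 0L
  while (length(bad)) {
    alt[bad] <- rbinom(length(bad), depth[bad], error_rate)
    bad <- bad[alt[bad] / depth[bad] >= 0.10]
    guard <- guard + 1L
    if (guard > 10000L) stop("cannot satisfy ref-hom band")
  }
  cbind(ref = depth - alt, alt = alt)
}

## depths for a homozygous-alternate sample: alternate fraction drawn
## around 0.95+, conditioned above the 90% AltHom band (planted
## homozygous variants represent sites satisfying the criteria, same
## rationale as the het band)
hom_alt_depths <- function(depth, error_rate) {
  p <- max(0.95, 1 - error_rate)
  alt <- rbinom(length(depth), depth, p)
  bad <- which(alt / depth <= 0.90)
  guard <- 0L
  while (length(bad)) {
    alt[bad] <- rbinom(length(bad), depth[bad], p)
    bad <- bad[alt[bad] / depth[bad] <= 0.90]
    guard <- guard + 1L
    if (guard > 10000L) stop("cannot satisfy hom-alt band")
  }
  cbind(ref = depth - alt, alt = alt)
}

#' Simulate a trio allele-depth table with planted variants
#'
#' Generates `n_sites` biallelic sites across the autosomal contigs of a
#' synthetic genome (plus optional background sites on excluded contigs),
#' planting inherited heterozygous variants, heterozygous and homozygous
#' de novo variants, and homozygous artifact sites inside annotated
#' repeat intervals.  All remaining sites are homozygous reference in
#' all three samples.  Truth labels are returned alongside.
#'
#' @param config a [trio_sim_config()].
#' @param genome a `synthetic_genome` (provides contig lengths, the gene
#'   model used for positional placement, and repeat intervals).
#' @param excluded_contigs contigs that receive only background sites
#'   (they are expected to be removed by [filter_sites()]).
#' @param n_excluded_sites number of background sites placed on
#'   `excluded_contigs` (in addition to `n_sites`).
#' @return list with `sites` (data.frame: `contig`, `pos`, `ref`, `alt`,
#'   `sire_ref`, `sire_alt`, `dam_ref`, `dam_alt`, `off_ref`, `off_alt`,
#'   `gq_sire`, `gq_dam`, `gq_off`) and `truth` (per-site label and,
#'   when requested, the planted positional class).
#' @export
simulate_trio_depths <- function(config, genome, excluded_contigs = NULL,
                                 n_excluded_sites = 0L) {
  stopifnot(inherits(config, "trio_sim_config"),
            inherits(genome, "synthetic_genome"))
  withr::with_seed(config$seed, {
    contigs <- names(genome$genome)
    auto <- setdiff(contigs, excluded_contigs)
    if (!length(auto)) stop("no autosomal contigs available")
    lens <- nchar(genome$genome)[auto]

    ## placement pools are restricted to the autosomal contigs so that
    ## planted (non-background) sites survive contig exclusion
    model <- genome$model
    on_auto <- function(gr) gr[as.character(
      GenomicRanges::seqnames(gr)) %in% auto]
    exonic_gr <- on_auto(model$exons)
    genic_gr <- on_auto(model$genes)
    rep_gr <- on_auto(genome$repeats)

    n_het <- config$n_denovo_het
    placed_classes <- NULL
    if (!is.null(names(n_het)) && length(n_het) > 1) {
      stopifnot(all(names(n_het) %in% c("intergenic", "intronic", "exonic")))
      placed_classes <- rep(names(n_het), times = n_het)
      n_denovo_het_total <- sum(n_het)
    } else {
      n_denovo_het_total <- as.integer(sum(n_het))
    }

    ## position pools ------------------------------------------------
    sample_positions <- function(n, where = c("any", "intergenic",
                                              "intronic", "exonic",
                                              "repeat")) {
      where <- match.arg(where)
      if (n == 0) return(data.frame(contig = character(0), pos = integer(0)))
      pick_from_gr <- function(gr) {
        if (!length(gr)) stop("no interval space for class '", where, "'")
        w <- GenomicRanges::width(gr)
        idx <- sample.int(length(gr), n, replace = TRUE, prob = w)
        data.frame(contig = as.character(GenomicRanges::seqnames(gr))[idx],
                   pos = GenomicRanges::start(gr)[idx] +
                     vapply(GenomicRanges::width(gr)[idx], function(wd)
                       sample.int(wd, 1L) - 1L, integer(1)))
      }
      switch(where,
        any = {
          ct <- sample(auto, n, replace = TRUE, prob = lens)
          data.frame(contig = ct,
                     pos = vapply(lens[ct], function(L)
                       sample.int(L, 1L), integer(1)))
        },
        exonic = pick_from_gr(exonic_gr),
        intronic = {
          intr <- GenomicRanges::setdiff(genic_gr, exonic_gr,
                                         ignore.strand = TRUE)
          pick_from_gr(intr)
        },
        intergenic = {
          tiles <- GenomicRanges::GRanges(auto, IRanges::IRanges(1, lens))
          inter <- GenomicRanges::setdiff(
            tiles, c(GenomicRanges::granges(genic_gr),
                     GenomicRanges::granges(rep_gr)),
            ignore.strand = TRUE)
          pick_from_gr(inter)
        },
        "repeat" = pick_from_gr(rep_gr))
    }

    plant <- list()
    if (config$n_inherited_het > 0)
      plant$inherited_het <- cbind(
        sample_positions(config$n_inherited_het, "any"),
        label = "inherited_het")
    if (n_denovo_het_total > 0) {
      if (is.null(placed_classes)) {
        ph <- sample_positions(n_denovo_het_total, "any")
        ph$placed_class <- NA_character_
      } else {
        ph <- do.call(rbind, lapply(unique(placed_classes), function(cl) {
          p <- sample_positions(sum(placed_classes == cl), cl)
          p$placed_class <- cl
          p
        }))
      }
      ph$label <- "denovo_het"
      plant$denovo_het <- ph
    }
    if (config$n_denovo_hom > 0)
      plant$denovo_hom <- cbind(
        sample_positions(config$n_denovo_hom, "intergenic"),
        label = "denovo_hom")
    if (config$n_artifact_hom_in_repeats > 0)
      plant$artifact_hom <- cbind(
        sample_positions(config$n_artifact_hom_in_repeats, "repeat"),
        label = "artifact_hom")

    planted <- if (length(plant)) {
      for (i in seq_along(plant))
        if (is.null(plant[[i]]$placed_class))
          plant[[i]]$placed_class <- NA_character_
      do.call(rbind, plant)
    } else {
      data.frame(contig = character(0), pos = integer(0),
                 label = character(0), placed_class = character(0))
    }

    n_bg <- config$n_sites - nrow(planted)
    bg <- sample_positions(n_bg, "any")
    if (n_excluded_sites > 0) {
      if (is.null(excluded_contigs) ||
          !length(intersect(excluded_contigs, contigs)))
        stop("n_excluded_sites > 0 requires excluded contigs in the genome")
      exc <- intersect(excluded_contigs, contigs)
      exlens <- nchar(genome$genome)[exc]
      ct <- sample(exc, n_excluded_sites, replace = TRUE, prob = exlens)
      bg <- rbind(bg, data.frame(
        contig = ct, pos = vapply(exlens[ct], function(L)
          sample.int(L, 1L), integer(1))))
    }
    bg$label <- "background"
    bg$placed_class <- NA_character_

    sites <- rbind(planted, bg)
    ## deduplicate identical (contig,pos) pairs — astronomically rare,
    ## but keeps sites unique by jittering duplicates by one base
    dup <- duplicated(sites[c("contig", "pos")])
    while (any(dup)) {
      sites$pos[dup] <- sites$pos[dup] + 1L
      dup <- duplicated(sites[c("contig", "pos")])
    }
    o <- order(sites$contig, sites$pos)
    sites <- sites[o, , drop = FALSE]
    rownames(sites) <- NULL
    n <- nrow(sites)

    ## alleles
    ref_al <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt_al <- vapply(ref_al, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))

    ## depths (>= 2 so every ratio is defined; depths 3 and 5 admit no
    ## integer count strictly inside the 40-60% band, so bump them)
    dp <- function() {
      d <- pmax(rpois(n, config$depth_mean), 2L)
      d[d %in% c(3L, 5L)] <- 6L
      d
    }
    d_sire <- dp(); d_dam <- dp(); d_off <- dp()
    er <- config$error_rate

    sire <- hom_ref_depths(d_sire, er)
    dam <- hom_ref_depths(d_dam, er)
    off <- hom_ref_depths(d_off, er)

    lab <- sites$label
    ih <- lab == "inherited_het"
    if (any(ih)) {
      ## one parent het (random which), offspring het
      from_sire <- runif(sum(ih)) < 0.5
      het_par <- function(idx, sel, d) {
        alt <- rbinom_het_band(d[idx][sel])
        cbind(ref = d[idx][sel] - alt, alt = alt)
      }
      sire[which(ih)[from_sire], ] <- het_par(ih, from_sire, d_sire)
      dam[which(ih)[!from_sire], ] <- het_par(ih, !from_sire, d_dam)
      alt_off <- rbinom_het_band(d_off[ih])
      off[ih, ] <- cbind(d_off[ih] - alt_off, alt_off)
    }
    dh <- lab == "denovo_het"
    if (any(dh)) {
      alt_off <- rbinom_het_band(d_off[dh])
      off[dh, ] <- cbind(d_off[dh] - alt_off, alt_off)
    }
    hm <- lab %in% c("denovo_hom", "artifact_hom")
    if (any(hm))
      off[hm, ] <- hom_alt_depths(d_off[hm], er)

    tab <- data.frame(
      contig = sites$contig, pos = sites$pos,
      ref = ref_al, alt = alt_al,
      sire_ref = sire[, "ref"], sire_alt = sire[, "alt"],
      dam_ref = dam[, "ref"], dam_alt = dam[, "alt"],
      off_ref = off[, "ref"], off_alt = off[, "alt"],
      gq_sire = 99L, gq_dam = 99L, gq_off = 99L,
      stringsAsFactors = FALSE)
    truth <- data.frame(contig = sites$contig, pos = sites$pos,
                        label = sites$label,
                        placed_class = sites$placed_class,
                        stringsAsFactors = FALSE)
    list(sites = tab, truth = truth)
  })
}

#' Write / read a trio depth table
#'
#' Plain TSV with the column layout of [simulate_trio_depths()].
#'
#' @param sites trio site data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_trio_table <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trio_table
#' @export
read_trio_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt", "sire_ref", "sire_alt",
            "dam_ref", "dam_alt", "off_ref", "off_alt")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("trio table lacks columns: ",
                         paste(miss, collapse = ", "))
  tab
}
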