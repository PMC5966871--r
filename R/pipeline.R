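## End-to-end orchestration: scenario presets that simulate every input
## with known truth, stage runners working from files or in-memory
## objects, and a JSON summary report with provenance.

#' Simulate the three-site paternal-transmission scenario
#'
#' A ~300 kb three-contig genome patterned on a documented
#' integration-site table: two forward piggyBac insertions on a chr4-like
#' contig and one on a chr6-like contig (the third contig is empty), with
#' the flanking genes named accordingly, sequenced at the requested
#' depth, error-free by default.
#'
#' @param seed RNG seed.
#' @param depth sequencing depth.
#' @param error_rate per-base substitution rate.
#' @return list with `genome` (`synthetic_genome`), `construct`,
#'   `planted` (`planted_genome`), `model` (named flanking genes),
#'   `sim` (reads + truth alignments + header).
#' @export
simulate_table1_scenario <- function(seed = 1L, depth = 30,
                                     error_rate = 0) {
  construct <- pb_example_construct()
  gen <- build_genome(c(chr4 = 100000L, chr6 = 100000L, chr10 = 100000L),
                      gc = 0.45, tsd_motif = "TTAA",
                      tsd_density_per_kb = 0.05,
                      telomere_tract_length = 0L,
                      genes_per_contig = 0L,
                      seed = derive_seed(seed, "table1-genome"))
  ## plant the TSD motifs and the flanking-gene layout explicitly
  sites <- data.frame(
    contig = c("chr4", "chr4", "chr6"),
    tsd_start = c(30000L, 70000L, 50000L),
    orientation = "forward", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sites)))
    gen$genome[[sites$contig[i]]] <-
      overwrite(gen$genome[[sites$contig[i]]], sites$tsd_start[i], "TTAA")
  gdf <- data.frame(
    contig = c("chr4", "chr4", "chr4", "chr4", "chr6", "chr6"),
    start = c(20000L, 35000L, 60000L, 75000L, 40000L, 55000L),
    end = c(25000L, 40000L, 65000L, 80000L, 45000L, 60000L),
    gene_id = c("TSGA13", "MKLN1", "ENSBTAG00000001198",
                "ENSBTAG00000046257", "DKK2", "GIMD1"),
    stringsAsFactors = FALSE)
  genes <- GenomicRanges::GRanges(gdf$contig,
                                  IRanges::IRanges(gdf$start, gdf$end),
                                  gene_id = gdf$gene_id)
  exons <- GenomicRanges::GRanges(gdf$contig,
                                  IRanges::IRanges(gdf$start, gdf$start + 999L),
                                  gene_id = gdf$gene_id)
  model <- gene_model(genes, exons)
  gen$model <- model
  planted <- plant_insertions(gen, construct, sites)
  sim <- simulate_reads(planted, depth = depth, error_rate = error_rate,
                        seed = derive_seed(seed, "table1-reads"))
  list(genome = gen, construct = construct, planted = planted,
       model = model, sim = sim)
}

#' Simulate the six-site fetal-genome scenario
#'
#' Same genome shape as [simulate_table1_scenario()] but with six
#' forward piggyBac insertions (two per contig), patterned on the
#' six-copy fetal sample.
#'
#' @inheritParams simulate_table1_scenario
#' @return same structure as [simulate_table1_scenario()].
#' @export
simulate_f1_2_scenario <- function(seed = 1L, depth = 30, error_rate = 0) {
  construct <- pb_example_construct()
  gen <- build_genome(c(chr1 = 100000L, chr2 = 100000L, chr3 = 100000L),
                      gc = 0.45, tsd_motif = "TTAA",
                      tsd_density_per_kb = 0.05,
                      telomere_tract_length = 0L,
                      genes_per_contig = 2L,
                      seed = derive_seed(seed, "f1-2-genome"))
  sites <- data.frame(
    contig = rep(c("chr1", "chr2", "chr3"), each = 2L),
    tsd_start = rep(c(30000L, 70000L), times = 3L),
    orientation = "forward", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sites)))
    gen$genome[[sites$contig[i]]] <-
      overwrite(gen$genome[[sites$contig[i]]], sites$tsd_start[i], "TTAA")
  planted <- plant_insertions(gen, construct, sites)
  sim <- simulate_reads(planted, depth = depth, error_rate = error_rate,
                        seed = derive_seed(seed, "f1-2-reads"))
  list(genome = gen, construct = construct, planted = planted,
       model = gen$model, sim = sim)
}

#' Pipeline configuration
#'
#' Collects stage parameters and input paths.  Defaults follow the
#' analysis settings of the modeled study design: Phred trim threshold 20, genotype
#' quality cutoff 60, 50 kb CNV windows, TTAGGG threshold k = 7, X/MT/
#' unplaced exclusions; integration-caller thresholds are this
#' package's documented defaults.
#'
#' @param out_dir output directory for stage files and the report.
#' @param seed global seed fanned out to per-stage seeds.
#' @param scenario optional simulation preset (`"table1"` or `"f1-2"`);
#'   when set, all inputs are simulated and analyzed end to end.
#' @param paths named list of input paths (`sam`, `genome`, `construct`,
#'   `gff`, `repeats`, `trio_table`) for running on existing files.
#' @param phred_threshold,gq_cutoff,window_size stage parameters
#'   mirroring the modeled study settings.
#' @param min_support,cluster_window,min_clip_length,min_identity
#'   integration-caller thresholds.
#' @param repeat_threshold_k,excluded_contigs,depth telomere threshold,
#'   contig exclusions and simulated sequencing depth.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, scenario = NULL,
                            paths = list(), phred_threshold = 20L,
                            gq_cutoff = 60L, window_size = 50000L,
                            min_support = 3L, cluster_window = 5L,
                            min_clip_length = 20L, min_identity = 0.9,
                            repeat_threshold_k = 7L,
                            excluded_contigs = c("X", "MT", "unplaced*"),
                            depth = 30) {
  if (!is.null(scenario))
    scenario <- match.arg(scenario, c("table1", "f1-2"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 scenario = scenario, paths = paths,
                 phred_threshold = phred_threshold, gq_cutoff = gq_cutoff,
                 window_size = window_size, min_support = min_support,
                 cluster_window = cluster_window,
                 min_clip_length = min_clip_length,
                 min_identity = min_identity,
                 repeat_threshold_k = repeat_threshold_k,
                 excluded_contigs = excluded_contigs, depth = depth),
            class = "pipeline_config")
}

config_hash <- function(config) {
  ## hash of the analysis-relevant configuration; output location is
  ## excluded so identical analyses hash identically wherever they run
  x <- unclass(config)
  x$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the stages in dependency order and writes stage TSVs plus a
#' JSON summary report to `config$out_dir`.  With a `scenario`, every
#' input is simulated with known truth first (insertion calling on the
#' simulated alignments, a trio table with planted de novo variants,
#' CNV and telomere scans of the simulated reads, and a two-sample
#' fluorescence comparison); rerunning with the same config and seed is
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return the summary report (list), invisibly; side effect: files
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  if (!is.null(config$scenario)) {
    scen <- if (config$scenario == "table1")
      simulate_table1_scenario(config$seed, depth = config$depth)
    else simulate_f1_2_scenario(config$seed, depth = config$depth)

    write_fasta(scen$planted$reference,
                file.path(config$out_dir, "host_reference.fa"))
    write_fasta(setNames(scen$construct$sequence, scen$construct$name),
                file.path(config$out_dir, "construct.fa"))
    write_sam(scen$sim$truth, scen$sim$header,
              file.path(config$out_dir, "alignments.sam"))
    write_gff(scen$model, file.path(config$out_dir, "genes.gff3"))
    write_bed(scen$genome$repeats, file.path(config$out_dir, "repeats.bed"))

    calls <- call_integrations(scen$sim$truth, scen$planted$reference,
                               scen$construct, model = scen$model,
                               min_clip_length = config$min_clip_length,
                               min_identity = config$min_identity,
                               min_support = config$min_support,
                               cluster_window = config$cluster_window)
    write_integration_calls(calls,
                            file.path(config$out_dir, "integration_calls.tsv"))
    report$integration <- list(
      n_calls = nrow(calls), n_planted = nrow(scen$planted$truth),
      tsd = unique(calls$tsd_sequence),
      orientations = unique(calls$orientation))

    ## trio stage on a simulated table tied to this genome
    tcfg <- trio_sim_config(n_sites = 20000L, depth_mean = 30,
                            n_inherited_het = 1000L, n_denovo_het = 147L,
                            n_artifact_hom_in_repeats = 2L,
                            seed = derive_seed(config$seed, "trio"))
    trio <- simulate_trio_depths(tcfg, scen$genome)
    write_trio_table(trio$sites,
                     file.path(config$out_dir, "trio_depths.tsv"))
    flt <- filter_sites(trio$sites, config$gq_cutoff,
                        config$excluded_contigs)
    dn <- call_denovo(flt)
    dn <- flag_repeat_artifacts(dn, scen$genome$repeats)
    dn <- annotate_position(dn, scen$model)
    write_trio_table(dn, file.path(config$out_dir, "denovo_calls.tsv"))
    dsum <- summarize_denovo(dn)
    dsum$mutation_rate <- mutation_rate(
      dsum$n_het, sum(nchar(scen$planted$reference)))
    report$denovo <- dsum

    ## CNV + telomere on the simulated alignments
    win <- window_counts(scen$sim$truth, scen$planted$reference,
                         window_size = min(config$window_size, 5000L))
    win <- copy_number(gc_normalize(win))
    write.table(win, file.path(config$out_dir, "cnv_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cnv_calls <- call_gain_loss(win)
    report$cnv <- list(median_copy_number = median(win$copy_number),
                       n_gain_loss_calls = nrow(cnv_calls))

    tel <- estimate_telomere_length(
      scen$sim$reads, sum(nchar(scen$planted$reference)),
      n_chromosome_ends = 2L * length(scen$planted$reference),
      repeat_threshold_k = config$repeat_threshold_k)
    report$telomere <- list(
      estimated_length_kb = tel$estimated_length_kb,
      telomeric_read_count = tel$telomeric_read_count,
      total_read_count = tel$total_read_count)

    ## fluorescence comparison: six- vs three-copy cell sets
    ia <- simulate_images(rep(6L, 10L), intensity_per_copy = 110,
                          seed = derive_seed(config$seed, "img-a"))
    ib <- simulate_images(rep(3L, 10L), intensity_per_copy = 100,
                          seed = derive_seed(config$seed, "img-b"))
    fc <- fold_change(measure_rois(ia$image, ia$rois),
                      measure_rois(ib$image, ib$rois))
    report$fluorescence <- list(fold_change = fc)
  } else {
    ## file-driven mode: run whichever stages have inputs
    p <- config$paths
    if (!is.null(p$sam) && !is.null(p$genome) && !is.null(p$construct)) {
      for (f in c(p$sam, p$genome, p$construct))
        if (!file.exists(f)) stop("missing input: ", f)
      genome <- read_fasta(p$genome)
      cons_seq <- read_fasta(p$construct)
      construct <- transposon_construct(names(cons_seq)[1],
                                        as.character(cons_seq)[1])
      model <- if (!is.null(p$gff)) read_gff(p$gff) else NULL
      aln <- read_sam(p$sam)$alignments
      calls <- call_integrations(aln, genome, construct, model = model,
                                 min_clip_length = config$min_clip_length,
                                 min_identity = config$min_identity,
                                 min_support = config$min_support,
                                 cluster_window = config$cluster_window)
      write_integration_calls(calls,
        file.path(config$out_dir, "integration_calls.tsv"))
      report$integration <- list(n_calls = nrow(calls))
      win <- window_counts(aln, genome, config$window_size)
      win <- copy_number(gc_normalize(win))
      write.table(win, file.path(config$out_dir, "cnv_windows.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$cnv <- list(median_copy_number = median(win$copy_number))
    }
    if (!is.null(p$trio_table)) {
      if (!file.exists(p$trio_table)) stop("missing input: ", p$trio_table)
      tab <- read_trio_table(p$trio_table)
      flt <- filter_sites(tab, config$gq_cutoff, config$excluded_contigs)
      dn <- call_denovo(flt)
      if (!is.null(p$repeats))
        dn <- flag_repeat_artifacts(dn, read_bed(p$repeats))
      if (!is.null(p$gff))
        dn <- annotate_position(dn, read_gff(p$gff))
      write_trio_table(dn, file.path(config$out_dir, "denovo_calls.tsv"))
      report$denovo <- summarize_denovo(dn)
    }
  }
  report$provenance <- list(
    package = "tgstab",
    version = as.character(utils::packageVersion("tgstab")),
    seed = config$seed,
    config_md5 = config_hash(config))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
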