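test_that("build_genome plants telomeres, motifs, genes and repeats", {
  gen <- build_genome(c(a = 30000L, b = 30000L), gc = 0.5,
                      telomere_tract_length = 3000L, seed = 5)
  for (s in gen$genome) {
    expect_identical(substr(s, 1, 3000), tgstab:::telomere_tract(3000L))
    expect_identical(substr(s, nchar(s) - 2999L, nchar(s)),
                     tgstab:::telomere_tract(3000L))
  }
  expect_gte(length(gen$model$genes), 2L)
  expect_gte(length(gen$repeats), 2L)
  expect_true(all(grepl("TTAA", gen$genome)))

  ## no tract when disabled
  gen0 <- build_genome(c(a = 30000L), telomere_tract_length = 0L, seed = 5)
  expect_false(startsWith(gen0$genome[["a"]], "TTAGGG"))

  ## GC content close to target on a 100 kb contig
  gen_gc <- build_genome(c(a = 100000L), gc = 0.5, seed = 6)
  expect_lt(abs(tgstab:::gc_fraction(gen_gc$genome[["a"]]) - 0.5), 0.02)

  ## over-long tract rejected
  expect_error(build_genome(c(a = 10000L), telomere_tract_length = 6000L),
               "telomere tract")
})

test_that("plant_insertions duplicates the TSD around the construct", {
  cons <- toy_construct()
  host <- toy_host()
  p <- nchar(host[["chr1"]]) %/% 2L
  planted <- plant_insertion(host, cons, "chr1", p, "forward")

  ## hand-constructed expected string: upstream+motif + construct +
  ## motif + downstream
  expected <- paste0(substr(host[["chr1"]], 1, p + 3L), cons$sequence,
                     "TTAA", substr(host[["chr1"]], p + 4L,
                                    nchar(host[["chr1"]])))
  expect_identical(planted$modified[["chr1"]], expected)

  ## length arithmetic: construct + motif
  expect_identical(nchar(planted$modified[["chr1"]]),
                   nchar(host[["chr1"]]) + nchar(cons$sequence) + 4L)

  ## TSD conservation: motif immediately flanks the construct
  ins_at <- p + 4L
  expect_identical(substr(planted$modified[["chr1"]], p, p + 3L), "TTAA")
  expect_identical(substr(planted$modified[["chr1"]],
                          ins_at + nchar(cons$sequence),
                          ins_at + nchar(cons$sequence) + 3L), "TTAA")

  ## reverse orientation inserts the reverse complement
  pr <- plant_insertion(host, cons, "chr1", p, "reverse")
  expect_identical(substr(pr$modified[["chr1"]], ins_at,
                          ins_at + nchar(cons$sequence) - 1L),
                   revcomp(cons$sequence))

  ## planting requires the motif
  expect_error(plant_insertion(host, cons, "chr1", p + 1L), "no TTAA motif")

  ## empty insertion list leaves the genome unchanged
  p0 <- plant_insertions(host, cons,
                         data.frame(contig = character(0),
                                    tsd_start = integer(0),
                                    orientation = character(0)))
  expect_identical(p0$modified, host)
})

test_that("simulated reads are exact substrings at zero error rate", {
  gen <- toy_host(len = 20000L)
  sim <- simulate_reads(gen, depth = 5, seed = 9)
  mod <- gen[["chr1"]]
  m1 <- sim$reads$mate == 1L
  expect_true(all(vapply(sim$reads$sequence[m1], grepl, logical(1),
                         x = mod, fixed = TRUE)))
  expect_true(all(vapply(revcomp(sim$reads$sequence[!m1]), grepl, logical(1),
                         x = mod, fixed = TRUE)))
  ## pair count follows depth * length / (2 * read length)
  expect_equal(nrow(sim$reads) / 2, 5 * 20000 / (2 * 150), tolerance = 0.01)
})

test_that("truth alignments at a junction carry the expected soft clips", {
  cons <- toy_construct()
  host <- toy_host(len = 20000L)
  p <- 10000L
  planted <- plant_insertion(host, cons, "chr1", p, "forward")
  segs <- planted$segments[["chr1"]]
  ## read starting 100 bases before the junction: 100M50S on the host,
  ## clipped bases equal to the construct start (oracle by hand from the
  ## piecewise map: host segment ends at p+3, construct block follows)
  a <- (p + 3L) - 100L + 1L
  map <- tgstab:::map_spans(a, a + 149L, segs, "chr1", cons$name,
                            nchar(cons$sequence))
  expect_identical(map$cigar, "100M50S")
  expect_identical(map$rname, "chr1")
  expect_identical(map$pos, a)
  mod_read <- substr(planted$modified[["chr1"]], a, a + 149L)
  expect_identical(substr(mod_read, 101L, 150L),
                   substr(cons$sequence, 1L, 50L))

  ## read mostly inside the construct maps to the construct contig
  b_start <- p + 4L + 10L
  map2 <- tgstab:::map_spans(b_start, b_start + 149L, segs, "chr1",
                             cons$name, nchar(cons$sequence))
  expect_identical(map2$rname, cons$name)
  expect_identical(map2$pos, 11L)

  ## replay invariant: at zero error, stored M bases match the target
  sim <- simulate_reads(planted, depth = 10, seed = 13)
  tr <- sim$truth
  targets <- c(planted$reference, setNames(cons$sequence, cons$name))
  clips <- tgstab:::cigar_clip_lengths(tr$cigar)
  mlen <- nchar(tr$seq) - clips$left - clips$right
  mseq <- substr(tr$seq, clips$left + 1L, clips$left + mlen)
  refseq <- substring(targets[tr$rname], tr$pos, tr$pos + mlen - 1L)
  expect_identical(mseq, unname(refseq))
})

test_that("simulators are reproducible under a fixed seed", {
  gen <- toy_host(len = 15000L)
  s1 <- simulate_reads(gen, depth = 3, seed = 77)
  s2 <- simulate_reads(gen, depth = 3, seed = 77)
  expect_identical(s1, s2)
  s3 <- simulate_reads(gen, depth = 3, seed = 78)
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))

  g1 <- build_genome(c(a = 12000L), seed = 4)
  g2 <- build_genome(c(a = 12000L), seed = 4)
  expect_identical(g1$genome, g2$genome)
})

test_that("error rate introduces roughly the requested substitutions", {
  gen <- toy_host(len = 20000L)
  sim0 <- simulate_reads(gen, depth = 3, error_rate = 0, seed = 21)
  sim1 <- simulate_reads(gen, depth = 3, error_rate = 0.01, seed = 21)
  ## same fragments drawn (same seed), so differences are the errors
  diffs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim0$reads$sequence, sim1$reads$sequence)
  rate <- sum(diffs) / sum(nchar(sim0$reads$sequence))
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
})

test_that("trio simulator plants the configured truth", {
  gen <- build_genome(c(chr1 = 40000L, chr2 = 40000L), seed = 31)
  cfg <- trio_sim_config(n_sites = 4000L, depth_mean = 30,
                         n_inherited_het = 300L, n_denovo_het = 25L,
                         n_denovo_hom = 3L, n_artifact_hom_in_repeats = 2L,
                         seed = 32)
  sim <- simulate_trio_depths(cfg, gen)
  expect_identical(nrow(sim$sites), 4000L)
  expect_identical(sum(sim$truth$label == "denovo_het"), 25L)
  expect_identical(sum(sim$truth$label == "denovo_hom"), 3L)

  ## artifact sites really are inside repeat intervals
  art <- sim$truth[sim$truth$label == "artifact_hom", ]
  expect_identical(nrow(art), 2L)
  gr <- GenomicRanges::GRanges(art$contig, IRanges::IRanges(art$pos, art$pos))
  expect_true(all(IRanges::overlapsAny(gr, gen$repeats)))

  ## no de novo truth when none requested
  cfg0 <- trio_sim_config(n_sites = 500L, n_inherited_het = 50L, seed = 33)
  sim0 <- simulate_trio_depths(cfg0, gen)
  expect_false(any(grepl("denovo", sim0$truth$label)))

  ## planted het alternate fractions center on one half
  cfgh <- trio_sim_config(n_sites = 1500L, depth_mean = 30,
                          n_denovo_het = 1200L, seed = 34)
  simh <- simulate_trio_depths(cfgh, gen)
  het <- simh$sites[simh$truth$label == "denovo_het", ]
  frac <- het$off_alt / (het$off_ref + het$off_alt)
  expect_lt(abs(mean(frac) - 0.5), 0.02)

  ## invalid configurations rejected
  expect_error(trio_sim_config(n_sites = 10L, n_denovo_het = 20L),
               "exceed")
})

test_that("Dre-rox recombination excises the first cassette", {
  cons <- pb_example_construct()
  rec <- apply_dre_recombination(cons)
  expect_identical(rec$features$name, c("rox", "RFP"))
  expect_false("GFP" %in% rec$features$name)
  ## excised length equals the distance between the rox starts
  f <- cons$features
  d <- f$start[f$name == "rox2"] - f$start[f$name == "rox1"]
  expect_identical(attr(rec, "excised_length"), d)
  expect_identical(nchar(rec$sequence), nchar(cons$sequence) - d)
  ## remaining rox is followed by the RFP payload
  expect_identical(substr(rec$sequence, rec$features$start[1],
                          rec$features$end[1]),
                   substr(cons$sequence, f$start[f$name == "rox1"],
                          f$end[f$name == "rox1"]))
  ## no rox -> unchanged with a warning
  sb <- sb_example_construct()
  expect_warning(unchanged <- apply_dre_recombination(sb), "rox")
  expect_identical(unchanged$sequence, sb$sequence)
})

test_that("image simulator conserves blob mass and scales linearly", {
  one <- simulate_images(3L, intensity_per_copy = 100, noise_sd = 0,
                         seed = 41)
  expect_lt(abs(sum(one$image) - 300), 1)
  roi <- one$rois
  m <- measure_roi(one$image, roi$x, roi$y, roi$width, roi$height)
  expect_lt(abs(m$integrated_density - 300), 1)

  ## doubling copy number doubles the truth signal
  two <- simulate_images(6L, intensity_per_copy = 100, noise_sd = 0,
                         seed = 41)
  expect_identical(two$truth$true_signal, 2 * one$truth$true_signal)

  ## zero cells -> pure background
  bg <- simulate_images(integer(0), background_level = 7, noise_sd = 0,
                        seed = 42)
  expect_true(all(bg$image == 7))
  expect_identical(nrow(bg$truth), 0L)

  ## impossible packing is detected
  expect_error(simulate_images(rep(1L, 500), shape = c(32L, 32L),
                               seed = 43, max_tries = 50L),
               "non-overlapping")
})
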