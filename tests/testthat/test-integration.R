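## Shared fixture: one forward insertion, error-free 30x reads.
junction_fixture <- function(orientation = "forward", seed = 51L,
                             depth = 30) {
  cons <- toy_construct()
  host <- toy_host(len = 20000L, seed = 52L)
  planted <- plant_insertion(host, cons, "chr1",
                             nchar(host[["chr1"]]) %/% 2L, orientation)
  sim <- simulate_reads(planted, depth = depth, seed = seed)
  list(cons = cons, host = host, planted = planted, sim = sim,
       p = nchar(host[["chr1"]]) %/% 2L)
}

test_that("soft-clip evidence matches construct ends around a junction", {
  fx <- junction_fixture()
  ev <- extract_softclip_evidence(fx$sim$truth, fx$cons)
  expect_gt(nrow(ev), 5)
  ## right clips carry the construct start (left end, forward);
  ## left clips carry the construct tail
  expect_setequal(unique(ev$matched_construct_end[ev$clip_side == "right"]),
                  "left")
  expect_setequal(unique(ev$matched_construct_end[ev$clip_side == "left"]),
                  "right")
  expect_true(all(ev$orientation == "forward"))
  expect_true(all(ev$match_identity == 1))
  ## junctions bracket the TSD: right clips at motif end, left at start
  expect_setequal(unique(ev$junction_position[ev$clip_side == "right"]),
                  fx$p + 3L)
  expect_setequal(unique(ev$junction_position[ev$clip_side == "left"]),
                  fx$p)

  ## clip-free stream yields nothing
  clean <- fx$sim$truth[fx$sim$truth$cigar == "150M", ]
  expect_identical(nrow(extract_softclip_evidence(clean, fx$cons)), 0L)

  ## clips that match neither end are ignored (scrambled construct)
  decoy <- withr::with_seed(99L,
    transposon_construct("decoy", tgstab:::random_dna(400),
                         "TTAA", end_length = 40L))
  ev_decoy <- extract_softclip_evidence(fx$sim$truth, decoy)
  expect_identical(nrow(ev_decoy), 0L)
})

test_that("clustered calls recover planted insertions with TSD and genes", {
  cons <- toy_construct()
  gen <- build_genome(c(chr1 = 40000L, chr2 = 40000L, chr3 = 40000L),
                      tsd_density_per_kb = 0.05, seed = 53)
  sites <- data.frame(contig = c("chr1", "chr2", "chr3"),
                      tsd_start = c(11000L, 21000L, 31000L),
                      orientation = "forward", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sites)))
    gen$genome[[sites$contig[i]]] <-
      tgstab:::overwrite(gen$genome[[sites$contig[i]]],
                         sites$tsd_start[i], "TTAA")
  planted <- plant_insertions(gen, cons, sites)
  sim <- simulate_reads(planted, depth = 30, seed = 54)
  calls <- call_integrations(sim$truth, planted$reference, cons)
  expect_identical(nrow(calls), 3L)
  expect_identical(calls$site_start, sites$tsd_start)
  expect_identical(calls$site_end, sites$tsd_start + 3L)
  expect_true(all(calls$tsd_sequence == "TTAA"))
  expect_true(all(calls$orientation == "forward"))
  expect_true(all(calls$support_reads >= 3))
})

test_that("support threshold and clustering window behave as documented", {
  fx <- junction_fixture()
  ev <- extract_softclip_evidence(fx$sim$truth, fx$cons)

  ## single supporting read with min_support 3 -> no call
  one <- ev[1, , drop = FALSE]
  expect_identical(nrow(cluster_and_call(one, fx$host, min_support = 3L)), 0L)
  expect_identical(nrow(cluster_and_call(one, fx$host, min_support = 1L)), 1L)

  ## evidence 2 bp apart merges into one cluster under window 5
  two <- ev[1:2, , drop = FALSE]
  two$junction_position <- c(1000L, 1002L)
  two$read_name <- c("a", "b")
  merged <- cluster_and_call(two, fx$host, min_support = 2L,
                             cluster_window = 5L)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$support_reads, 2L)

  ## raising min_support never increases the number of calls
  n_calls <- vapply(1:6, function(ms)
    nrow(cluster_and_call(ev, fx$host, min_support = ms)), integer(1))
  expect_true(all(diff(n_calls) <= 0))

  ## empty evidence -> empty calls
  expect_identical(nrow(cluster_and_call(ev[0, ], fx$host)), 0L)
})

test_that("reverse-orientation insertions are reported reverse", {
  fx <- junction_fixture(orientation = "reverse")
  calls <- call_integrations(fx$sim$truth, fx$host, fx$cons,
                             min_support = 2L)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$orientation, "reverse")
  expect_identical(calls$tsd_sequence, "TTAA")
  expect_identical(calls$site_start, fx$p)
})

test_that("flanking-gene annotation handles between, boundary and genic", {
  model <- toy_model()
  base <- data.frame(host_contig = "chr1", site_start = 3000L,
                     site_end = 3003L, orientation = "forward",
                     tsd_sequence = "TTAA", support_reads = 5L,
                     ambiguous = FALSE, five_prime_gene = NA_character_,
                     three_prime_gene = NA_character_, genic = FALSE,
                     stringsAsFactors = FALSE)
  ## between A and B
  got <- annotate_flanking_genes(base, model)
  expect_identical(got$five_prime_gene, "A")
  expect_identical(got$three_prime_gene, "B")
  ## no upstream gene on the contig
  up <- base; up$site_start <- 100L; up$site_end <- 103L
  got_up <- annotate_flanking_genes(up, model)
  expect_identical(got_up$five_prime_gene, "none")
  expect_identical(got_up$three_prime_gene, "A")
  ## inside a gene: both sides report it, flagged genic
  g <- base; g$site_start <- 1500L; g$site_end <- 1503L
  got_g <- annotate_flanking_genes(g, model)
  expect_identical(got_g$five_prime_gene, "A")
  expect_identical(got_g$three_prime_gene, "A")
  expect_true(got_g$genic)
})

test_that("the reference flanking-gene layout is reproduced on its fixture", {
  scen <- simulate_table1_scenario(seed = 3)
  calls <- call_integrations(scen$sim$truth, scen$planted$reference,
                             scen$construct, model = scen$model)
  expect_identical(nrow(calls), 3L)
  expect_identical(calls$five_prime_gene[1], "TSGA13")
  expect_identical(calls$three_prime_gene[1], "MKLN1")
  expect_identical(calls$five_prime_gene[3], "DKK2")
  expect_identical(calls$three_prime_gene[3], "GIMD1")
})

test_that("junction report concatenates flank, TSD and oriented end", {
  fx <- junction_fixture()
  calls <- call_integrations(fx$sim$truth, fx$host, fx$cons)
  expect_identical(nrow(calls), 1L)
  jr <- junction_report(calls, fx$host, fx$cons, flank = 50L)
  expect_true(grepl(paste0("TTAA", substr(fx$cons$sequence, 1, 40)), jr,
                    fixed = TRUE))
  ## zero flank starts at the TSD
  jr0 <- junction_report(calls, fx$host, fx$cons, flank = 0L)
  expect_true(startsWith(jr0, "TTAA"))
  ## reverse call uses the reverse-complemented construct end
  fr <- junction_fixture(orientation = "reverse")
  calls_r <- call_integrations(fr$sim$truth, fr$host, fr$cons,
                               min_support = 2L)
  jr_r <- junction_report(calls_r, fr$host, fr$cons, flank = 10L)
  expect_true(grepl(revcomp(fr$cons$right_end), jr_r, fixed = TRUE))
})

test_that("planted insertions are recovered across seeds without spurious calls", {
  cons <- toy_construct()
  host <- toy_host(len = 15000L, seed = 61L)
  p <- nchar(host[["chr1"]]) %/% 2L
  planted <- plant_insertion(host, cons, "chr1", p, "forward")
  for (seed in 101:106) {
    sim <- simulate_reads(planted, depth = 25, seed = seed)
    calls <- call_integrations(sim$truth, host, cons)
    expect_identical(nrow(calls), 1L)
    expect_lte(abs(calls$site_start - p), 2L)
    expect_identical(calls$tsd_sequence, "TTAA")
  }
})
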