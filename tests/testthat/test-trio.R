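test_that("genotype classification reproduces the depth-ratio bands", {
  expect_identical(as.character(classify_genotype(30, 0)), "RefHom")
  expect_identical(as.character(classify_genotype(15, 15)), "Hetero")
  expect_identical(as.character(classify_genotype(1, 29)), "AltHom")
  expect_identical(as.character(classify_genotype(10, 20)), "Ambiguous")
  ## boundary ratios are strict: exactly 90%, 40%, 60% are Ambiguous
  expect_identical(as.character(classify_genotype(9, 1)), "Ambiguous")
  expect_identical(as.character(classify_genotype(4, 6)), "Ambiguous")
  expect_identical(as.character(classify_genotype(6, 4)), "Ambiguous")
  expect_error(classify_genotype(0, 0), "zero total depth")
  expect_error(classify_genotype(-1, 5), "negative")
})

test_that("every depth pair maps to exactly one genotype class", {
  grid <- expand.grid(ref = 0:40, alt = 0:40)
  grid <- grid[grid$ref + grid$alt > 0, ]
  cls <- classify_genotype(grid$ref, grid$alt)
  expect_false(anyNA(cls))
  ## bands are mutually exclusive: recompute membership independently
  r <- grid$ref / (grid$ref + grid$alt)
  in_ref <- r > 0.90
  in_het <- r > 0.40 & r < 0.60
  in_alt <- (1 - r) > 0.90
  expect_true(all(in_ref + in_het + in_alt <= 1))
  expect_identical(as.character(cls) == "Ambiguous",
                   !(in_ref | in_het | in_alt))
})

test_that("site filtering honors quality cutoff and contig exclusions", {
  tab <- rbind(trio_site("chr1"), trio_site("X"), trio_site("MT"),
               trio_site("unplaced_001"), trio_site("chr2", gq = 59L))
  flt <- filter_sites(tab, 60, c("X", "MT", "unplaced*"))
  expect_identical(flt$contig, "chr1")
  ## no exclusions, no quality columns -> unchanged
  bare <- tab[, !grepl("^gq_", names(tab))]
  expect_identical(filter_sites(bare, 60, character(0)), bare)
})

test_that("de novo calling requires RefHom parents and a clean offspring class", {
  ## het de novo: parents >90% ref, offspring at 48.3% ref
  s1 <- trio_site(sire = c(30L, 0L), dam = c(28L, 1L), off = c(14L, 15L))
  got <- call_denovo(s1)
  expect_identical(nrow(got), 1L)
  expect_identical(got$offspring_class, "Hetero")
  ## inherited: a het parent blocks the call
  s2 <- trio_site(sire = c(15L, 15L), off = c(14L, 15L))
  expect_identical(nrow(call_denovo(s2)), 0L)
  ## ambiguous offspring suppresses the call
  s3 <- trio_site(off = c(20L, 10L))
  expect_identical(nrow(call_denovo(s3)), 0L)
  ## homozygous de novo
  s4 <- trio_site(off = c(1L, 29L))
  got4 <- call_denovo(s4)
  expect_identical(got4$offspring_class, "AltHom")
  ## empty input passes through
  expect_identical(nrow(call_denovo(s1[0, ])), 0L)
})

test_that("repeat-artifact flags mark exactly the calls inside intervals", {
  reps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500L, 600L))
  calls <- call_denovo(rbind(
    trio_site(pos = 550L, off = c(1L, 29L)),
    trio_site(pos = 700L, off = c(1L, 29L))))
  flagged <- flag_repeat_artifacts(calls, reps)
  expect_identical(flagged$repeat_artifact, c(TRUE, FALSE))
  ## empty repeat set -> no flags
  none <- flag_repeat_artifacts(calls, GenomicRanges::GRanges())
  expect_false(any(none$repeat_artifact))
})

test_that("positional annotation applies exonic > intronic > intergenic", {
  model <- toy_model()
  calls <- call_denovo(rbind(
    trio_site(pos = 1100L, off = c(14L, 15L)),   # in exon of A
    trio_site(pos = 1500L, off = c(14L, 15L)),   # in A, outside exon
    trio_site(pos = 9000L, off = c(14L, 15L))))  # outside all genes
  got <- annotate_position(calls, model)
  expect_identical(got$positional_class, c("exonic", "intronic",
                                           "intergenic"))
})

test_that("mutation rate is the count over callable positions", {
  expect_identical(mutation_rate(0, 1e9), 0)
  expect_equal(mutation_rate(100, 1e9), 1e-7)
  ## the reported order of magnitude arises from a plausible genome-
  ## scale denominator
  expect_equal(mutation_rate(149, 2.651e9), 5.62e-8, tolerance = 1e-3)
  expect_error(mutation_rate(10, 0), "positive")
  expect_error(mutation_rate(-1, 10), "non-negative")
})

test_that("planted trio variants are recovered without false positives", {
  gen <- build_genome(c(chr1 = 40000L, chr2 = 40000L), seed = 71)
  hits <- vapply(1:8, function(seed) {
    cfg <- trio_sim_config(n_sites = 3000L, depth_mean = 30,
                           n_inherited_het = 300L, n_denovo_het = 20L,
                           error_rate = 0.01, seed = seed)
    sim <- simulate_trio_depths(cfg, gen)
    dn <- call_denovo(filter_sites(sim$sites))
    key_call <- paste(dn$contig, dn$pos)
    key_true <- paste(sim$truth$contig, sim$truth$pos)
    ## no calls at inherited or background sites
    expect_length(setdiff(key_call,
                          key_true[sim$truth$label == "denovo_het"]), 0)
    sum(dn$offspring_class == "Hetero")
  }, numeric(1))
  expect_true(mean(hits == 20) >= 0.95)
})

test_that("a minimal VCF round-trips into the trio table layout", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SIRE", "DAM", "OFF", sep = "\t"),
    paste("chr1", "101", ".", "A", "G", ".", "PASS", ".", "GT:AD:GQ",
          "0/0:30,0:99", "0/0:28,1:99", "0/1:14,15:80", sep = "\t"),
    paste("chr1", "202", ".", "C", "T,G", ".", "PASS", ".", "GT:AD:GQ",
          "0/0:30,0:99", "0/0:30,0:99", "0/0:30,0:99", sep = "\t")), vcf)
  tab <- suppressMessages(read_trio_vcf(vcf))
  expect_identical(nrow(tab), 1L)   # multi-allelic record dropped
  expect_identical(tab$off_alt, 15L)
  expect_identical(tab$gq_off, 80)
  dn <- call_denovo(tab)
  expect_identical(dn$offspring_class, "Hetero")
})

test_that("trio table TSV round trip preserves the records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- rbind(trio_site("chr1", 100L), trio_site("chr2", 200L))
  write_trio_table(tab, path)
  expect_identical(read_trio_table(path), tab)
  writeLines("contig\tpos", path)
  expect_error(read_trio_table(path), "lacks columns")
})
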