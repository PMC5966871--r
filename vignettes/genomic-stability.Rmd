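---
title: "Assessing transgenic genomes: methods and design notes"
author: "tgstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing transgenic genomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgstab)
```

This vignette is the package's account of the science it implements:
the models and procedures, the parameters that matter and why their
defaults are what they are, what the synthetic-data layer does and
does not emulate, and the numerical and design choices made where the
problem left them open.

## Integration-site detection from soft clips

A transposase inserts its cargo at a short target motif and
duplicates it, so the integrated locus reads
`...host | TSD | construct | TSD | host...` (TSD `TTAA` for piggyBac,
`TA` for Sleeping Beauty).  When reads from such a locus are aligned
to the *unmodified* host reference plus a construct contig, reads
crossing the left junction align to the host up to the end of the
motif and carry the construct prefix as a right soft clip; reads
crossing the right junction align from the motif start onward and
carry the construct suffix as a left soft clip.  The two clip
boundaries therefore bracket the duplicated motif exactly — the
signature `cluster_and_call()` exploits.

The caller proceeds in three steps:

1. `extract_softclip_evidence()` keeps host-mapped, non-duplicate
   reads with a terminal clip of at least `min_clip_length` (default
   20) bases whose clipped tail matches a construct end by ungapped
   identity of at least `min_identity` (default 0.9).  Matching is
   intentionally ungapped: junction tails of genuine integrations are
   near-exact copies of the construct terminus, so full local
   alignment buys nothing but false flexibility.
2. Evidence within `cluster_window` (default 5) bases merges into a
   candidate, which becomes a call at `min_support` (default 3)
   distinct reads.  The defaults are chosen to be stringent at 30×
   coverage, where each junction attracts roughly ten clipped reads
   per side; all four are configurable.
3. The TSD is located by exact motif search within one motif length
   of the junction cluster.  When no motif is found, the call is kept
   with an empty TSD and a ±2 bp interval around the clip consensus —
   real sites should not be discarded over motif-level noise.

Orientation is a deterministic convention: the construct *left* end
joining the host at a *right* clip means forward; the right end at a
right clip means reverse (and mirrored for left clips).  Clusters
with conflicting assignments are flagged ambiguous and reported with
the majority vote.  `annotate_flanking_genes()` reports the nearest
gene ending before the site and the nearest starting after it; a call
inside a gene reports that gene on both sides with a `genic` flag.

## Trio genotype classification and de novo search

Genotypes are classified from biallelic allele depths:

* RefHom: ref/(ref+alt) > 0.90
* Hetero: 0.40 < ref/(ref+alt) < 0.60
* AltHom: alt/(ref+alt) > 0.90

All inequalities are strict — a literal reading of the criteria — so
ratios exactly at 0.90, 0.40 or 0.60 fall into the fourth class,
Ambiguous.  The four classes partition every positive-depth site,
which the test suite checks over an exhaustive depth grid.  A de novo
call requires both parents RefHom and the offspring Hetero or AltHom;
an Ambiguous member anywhere suppresses the call rather than being
imputed — the conservative choice, since remaining variants are
*searched* as de novo, not modeled.  Sites are pre-filtered by
genotype quality (≥ 60 in all three samples; records without the
field pass) and by contig exclusion (X, MT, `unplaced*` — prefix
wildcards supported).  Homozygous calls overlapping LTR-repeat
annotation are flagged artifacts, mirroring the observation that such
calls are mapping errors in repetitive sequence.  Positional classes
use strict precedence exonic > intronic > intergenic.
`mutation_rate(n, callable)` is plain division; the callable-genome
denominator is a user input because no standard value exists — the
reported per-generation rate of ~5.6 × 10⁻⁸ corresponds to a count
near 150 over a ~2.65 Gb callable genome, which the unit tests use as
an arithmetic check only.

## Copy-number scan

Reads are binned by leftmost mapped base into fixed windows (50 kb
default, matching the modeled study setting; the width is a parameter
both because one figure legend cites 10 kb windows and because the
synthetic genomes here are small — tests and the acceptance analysis
use 2–5 kb windows on 100–300 kb genomes).  GC normalization is a
transparent median-ratio scheme standing in for black-box correction
in dedicated CNV callers: windows are binned by GC in 2% steps and
counts are scaled by global-median / bin-median, with empty or
zero-median bins falling back to scale 1.  Copy number is
2 · normalized / median(normalized) over autosomal windows, i.e. the
diploid baseline of two; gains and losses are called above 2.5 and
below 1.5 and merged across adjacent windows.  No segmentation
algorithm is applied — single-window calls merged by adjacency are
adequate at these scales and keep the scan auditable.

## Telomere length

A read is telomeric if it contains at least k non-overlapping copies
of `TTAGGG` or its reverse complement; k = 7 is the conventional
threshold for 100 bp+ reads (the motif cannot overlap itself, so
plain pattern counting suffices).  The estimator

  length (kb) = telomeric reads × genome length /
                (total reads × chromosome ends × 1000)

is the abundance estimator behind read-frequency telomere callers,
without GC stratification (a deliberate non-goal).  It is unbiased up
to an edge term of ~45 bases per end — reads must overlap a tract by
seven motif copies to count — so a 10 kb tract is underestimated by
under 1%, well inside sampling noise at 30×.  Because the statistic
is a read *fraction*, it is invariant to total depth, which the tests
verify at 20× vs 40×.  The reported length value of 10.23 carries no
unit; this package interprets it as kilobases per chromosome end and
documents that assumption wherever the value is used.

## Fluorescence quantification

`measure_roi()` implements the ImageJ measurement triplet: area
(pixel count), mean gray value, integrated density (their product,
identically the pixel sum).  Fold change is the ratio of mean per-ROI
integrated densities between two samples, with all ROIs equally sized
— free-form ROIs and background subtraction are out of scope, matching
the fixed-square measurement procedure being modeled.

## What the simulators emulate — and what they do not

`build_genome()` produces uniform-composition random contigs with
phase-aligned terminal `TTAGGG` tracts, planted TSD motifs, a small
two-exon gene model per contig and one LTR interval per contig.  It
does not emulate repeat families, GC isochores, or realistic gene
density; conclusions from passing tests are about the *callers'
correctness given their evidence model*, not about performance on real
bovine data (mappability, PCR bias and alignment artifacts are
untested here).

`simulate_reads()` draws fixed-length fragments (350 bp, 2 × 150 bp
ends, matching the modeled library) uniformly from the modified
genome and emits truth alignments from a piecewise coordinate map
rather than an external aligner: reads majority-inside the construct
map to the construct contig; junction reads get the minority side
soft-clipped.  This reproduces exactly the evidence pattern the
caller consumes while keeping the package dependency-free; users
wanting full realism can align the emitted FASTQ themselves.
Substitution errors are uniform; indel errors and quality decay are
not modeled.

`simulate_trio_depths()` draws per-sample depth as Poisson around the
mean (floored at 2, with depths 3 and 5 bumped to 6 since no integer
count lies strictly inside the 40–60% band at those depths).
Planted genotype classes are sampled *conditioned on their
classification band*: heterozygous alternate depths are
Binomial(depth, 0.5) restricted to the open 40–60% band, homozygous
alternates Binomial(depth, ≥0.95) above 90%, and reference
homozygotes below 10% alternate.  The rationale: a planted truth
label asserts a variant that *satisfies the depth-ratio criteria* —
reported de novo counts are themselves post-classification counts —
so truth recovery is exact by construction at zero error rate, and
the classifier's bands are exercised by the boundary grid tests
rather than by sampling noise.  An unconditioned binomial would make
~36% of true heterozygotes fall outside the strict band at 30× and
turn every count comparison into a statement about binomial tails
instead of about the classifier.

`simulate_images()` renders each cell as a discrete Gaussian blob
*normalized to unit mass*, so integrated signal is conserved exactly
(copy number × per-copy intensity), on a constant background with
additive Gaussian noise clamped at zero.  Pixels are non-negative
reals in memory and quantized only on PGM write.  In the two-sample
comparison the noise level is set to 5% of the dimmer sample's mean
within-ROI signal per pixel: because ROI sums are compared as a
*ratio*, any additive offset (including the rectification bias of
clamped noise) biases the ratio toward 1, and this noise scale keeps
that bias below 1% while remaining a visible noise floor.  Cell
placement is rejection sampling with bounded retries; overlap is an
error, not a warning.

`apply_dre_recombination()` excises between the first same-orientation
pair of rox features, leaving a single rox (renamed `rox`) followed by
the downstream payload; inverted-repeat pairs are out of scope, as
the modeled construct carries a direct repeat.

## Numerical and interface choices

* **Coordinates.**  Internally everything is 1-based inclusive on
  GRanges/IRanges — the Bioconductor convention — with format
  conventions honored at I/O edges (BED 0-based half-open on disk,
  GFF3 and SAM 1-based).  Round-trip identity is tested per format.
* **Read trimming.**  The modeled analysis names a trimming tool but
  not an algorithm; `trim_reads()` uses a 10-base sliding window cut
  where mean quality first reaches the threshold (default Phred 20),
  strips sub-threshold bases at the cut edge, drops reads under
  50 bases, and iterates to a fixpoint so trimming is provably
  idempotent.  Exact parity with any specific trimmer is a non-goal.
* **SAM.**  Text SAM only, with the paired/strand/mate/duplicate flag
  bits — the subset the counters consume.  Duplicate-flagged reads are
  skipped by the window counter and the evidence extractor.
* **Seeds.**  Every simulator takes a seed and restores RNG state
  (`withr::with_seed`); `derive_seed()` fans a global seed into
  per-stage seeds so pipeline stages can be rerun independently.
  Identical config + seed gives byte-identical outputs, tested.
* **Problem sizes.**  The validation analyses use 100–300 kb genomes
  at 20–30×, 100,000-site trio tables, and 128×128 images — sizes
  chosen so the full suite runs in about a minute while every
  estimator operates in its asymptotic regime (thousands of reads per
  window median, ~8,000 telomeric reads, 20 cells per image set).

## Known limitations

* Discordant-pair (split-insert) evidence is not used; detection
  relies on soft clips alone, which is ample at 30× with 150 bp reads
  but would degrade for constructs shorter than a read.
* Multi-allelic sites are out of scope for the trio classifier
  (biallelic ref+alt denominator); the VCF reader drops them.
* The CNV scan has no segmentation model and assumes a mostly-diploid
  genome for its baseline median.
* The telomere estimator assumes telomeric reads arise only from
  terminal tracts — interstitial telomeric repeats would inflate it.
* Fluorescence comparison assumes equal-size ROIs and proportional
  rendering; per-pixel saturation and optical aberrations are not
  modeled.
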