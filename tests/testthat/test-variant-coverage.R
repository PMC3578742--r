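# constructed single-column pileups with a chosen VAF
mk_aln <- function(region, n_ref, n_alt, pos0 = 100L) {
  ref_read <- substr(region$sequence, pos0 + 1L, pos0 + 36L)
  alt_read <- ref_read
  ref11 <- substr(ref_read, 11, 11)
  substr(alt_read, 11, 11) <- setdiff(c("A", "C", "G", "T"), ref11)[1]
  n <- n_ref + n_alt
  data.frame(
    qname = sprintf("q%03d", seq_len(n)), mate = 1L, rname = region$name,
    pos0 = pos0, strand = "+", nm = c(rep(0L, n_ref), rep(1L, n_alt)),
    uniq = "unique",
    seq = c(rep(ref_read, n_ref), rep(alt_read, n_alt)),
    qual = strrep("I", 36), stringsAsFactors = FALSE
  )
}

test_that("pileup counts always sum to depth", {
  aln <- fixture_aln("het")
  region <- fixture_region()
  counts <- pileup_counts(aln, region)
  depth <- colSums(counts)
  # independent depth: count unique reads overlapping sampled columns
  sub <- aln[aln$uniq == "unique", ]
  set.seed(5)
  for (p in sample.int(nchar(region$sequence), 25)) {
    expect_equal(as.integer(depth[p]),
                 sum(sub$pos0 <= p - 1L & sub$pos0 + 36L > p - 1L),
                 ignore_attr = TRUE)
  }
  n_unique <- sum(aln$uniq == "unique")
  expect_identical(sum(counts), n_unique * 36L)
  # every base lands inside the region
  expect_identical(ncol(counts), nchar(region$sequence))
})

test_that("VAF thresholds behave per preset: 0.30 calls at relaxed only", {
  region <- build_reference(2000, 0, seed = 21, name = "r")
  aln <- mk_aln(region, 7, 3)  # VAF 0.30, depth 10
  relaxed <- pileup_and_call(aln, region, preset = "relaxed", min_depth = 8)
  expect_identical(nrow(relaxed), 1L)
  expect_identical(relaxed$position, 111L)
  expect_identical(relaxed$genotype, "het")
  expect_equal(relaxed$vaf, 0.3)
  initial <- pileup_and_call(aln, region, preset = "initial", min_depth = 8)
  expect_identical(nrow(initial), 0L)

  hom <- pileup_and_call(mk_aln(region, 1, 9), region, preset = "initial",
                         min_depth = 8)
  expect_identical(hom$genotype, "hom_alt")

  shallow <- pileup_and_call(mk_aln(region, 2, 1), region,
                             preset = "relaxed", min_depth = 5)
  expect_identical(nrow(shallow), 0L)  # depth 3 < min_depth
})

test_that("the 0.40-threshold call set is a subset of the 0.25 set", {
  region <- fixture_region()
  aln <- fixture_aln("het", seed = 3, coverage = 50, error_rate = 0.005)
  initial <- pileup_and_call(aln, region, preset = "initial")
  relaxed <- pileup_and_call(aln, region, preset = "relaxed")
  expect_true(all(initial$position %in% relaxed$position))
})

test_that("planted het SNVs at 50x are recovered with high sensitivity", {
  region <- build_reference(10000, 0, seed = 41, name = "snv")
  # mutant haplotype = reference with 20 planted substitutions
  hap <- region$sequence
  set.seed(42)
  snv_pos <- sort(sample(seq(200, 9800, by = 450), 20))
  for (p in snv_pos) {
    substr(hap, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(hap, p, p))[1]
  }
  mut <- list(haplotype = hap,
              truth = list(genotype = "het", insertion_position = 1L,
                           tsd_length = 0L, family = "snv",
                           orientation = "+", element_length = 0L,
                           junction_left0 = 0L, junction_right0 = 0L))
  pairs <- simulate_read_pairs(region, "het", mutant = mut, coverage = 50,
                               error_rate = 0, capture = FALSE, seed = 43)
  aln <- align_pairs(pairs, region)
  calls <- pileup_and_call(aln, region, preset = "relaxed")
  recovered <- sum(snv_pos %in% calls$position)
  expect_gte(recovered / length(snv_pos), 0.95)
  # no spurious calls away from the planted sites on error-free data
  expect_identical(sum(!calls$position %in% snv_pos), 0L)
})

test_that("coverage statistics match construction", {
  region <- build_reference(10000, 0, seed = 9, name = "cov")
  empty <- coverage_stats(
    data.frame(qname = character(), mate = integer(), rname = character(),
               pos0 = integer(), strand = character(), nm = integer(),
               uniq = character(), seq = character(), qual = character(),
               stringsAsFactors = FALSE),
    region
  )
  expect_identical(empty$covered_bases, 0L)
  expect_identical(empty$fraction_covered, 0)
  expect_identical(empty$mean_depth, 0)

  pairs <- simulate_read_pairs(region, "wt", coverage = 50,
                               error_rate = 0, seed = 11)
  aln <- align_pairs(pairs, region)
  classes <- classify_pairs(aln)
  cs <- coverage_stats(aln, region, classes = classes)
  expect_lt(abs(cs$mean_depth - 50) / 50, 0.10)
  expect_gte(cs$proper_pair_fraction, 0.99)
  expect_identical(sum(cs$histogram$n_positions), 10000L)
  # histogram mass equals positions; mean from histogram midpoint is sane
  expect_error(coverage_stats(aln, region, interval = c(5, 2)), "interval")
})

test_that("pileups reject alignments against a different reference", {
  region <- build_reference(2000, 0, seed = 21, name = "r")
  aln <- mk_aln(region, 3, 0)
  aln$rname <- "other_chrom"
  expect_error(pileup_and_call(aln, region), "do not match")
})

test_that("covered intervals export as BED and reimport intact", {
  region <- build_reference(2000, 0, seed = 21, name = "r")
  aln <- rbind(mk_aln(region, 4, 0, pos0 = 100L),
               mk_aln(region, 4, 0, pos0 = 500L))
  cs <- coverage_stats(aln, region)
  f <- tempfile(fileext = ".bed")
  write_covered_bed(cs, region, f)
  gr <- rtracklayer::import(f, format = "BED")
  expect_identical(length(gr), 2L)
  expect_identical(GenomicRanges::start(gr), c(101L, 501L))
  expect_identical(GenomicRanges::end(gr), c(136L, 536L))
})

test_that("tandem repeat counting finds the leftmost maximal run", {
  s <- paste0("GGCCA", strrep("TATC", 16), "GGTACCA", strrep("TATC", 3))
  res <- count_tandem_repeats(s, "TATC")
  expect_identical(res$copies, 16L)
  expect_identical(res$start, 6L)

  expect_identical(count_tandem_repeats("GGCCAATT", "TATC")$copies, 0L)
  expect_identical(count_tandem_repeats("ATATAT", "AT")$copies, 3L)
  # leftmost run wins ties
  tie <- paste0("G", strrep("CA", 4), "TTT", strrep("CA", 4))
  expect_identical(count_tandem_repeats(tie, "CA")$start, 2L)
  expect_error(count_tandem_repeats("ACGT", ""), "empty")
})

test_that("a 15- vs 16-copy microsatellite distinguishes the two alleles", {
  flank_l <- "GGATCCTTGA"; flank_r <- "TTGACCGGTA"
  wt_allele <- paste0(flank_l, strrep("TATC", 15), flank_r)
  mut_allele <- paste0(flank_l, strrep("TATC", 16), flank_r)
  expect_identical(count_tandem_repeats(wt_allele, "TATC")$copies, 15L)
  expect_identical(count_tandem_repeats(mut_allele, "TATC")$copies, 16L)
})
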