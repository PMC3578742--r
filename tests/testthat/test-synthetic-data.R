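test_that("build_reference hits the requested repeat fraction and rejects bad input", {
  region <- build_reference(10000, 0.49, 3, seed = 1)
  planted <- sum(IRanges::width(IRanges::reduce(
    GenomicRanges::ranges(region$repeats)
  )))
  expect_lt(abs(planted - 4900), 490)  # within 10% of target
  expect_equal(repeat_fraction(region), planted / 10000)

  bare <- build_reference(1000, 0, seed = 1)
  expect_identical(length(bare$repeats), 0L)
  expect_identical(repeat_fraction(bare), 0)

  expect_error(build_reference(0, 0.5), "positive")
  expect_error(build_reference(10000, 1.5), "\\[0, 1\\]")
  expect_error(build_reference(500, 0.4), ">= 1000")
})

test_that("planted repeat copies genuinely multi-map", {
  region <- build_reference(10000, 0.49, 3, seed = 1)
  gr <- region$repeats
  fam <- names(which.max(table(gr$family)))
  copy <- gr[gr$family == fam][1]
  # with per-copy divergence, some (not necessarily all) windows of a copy
  # stay within the mismatch budget of a sibling copy
  starts <- seq(GenomicRanges::start(copy),
                GenomicRanges::end(copy) - 35L, by = 12L)
  reads <- substring(region$sequence, starts, starts + 35L)
  res <- align_reads(reads, region, max_mismatch = 2L)
  expect_gte(sum(res$summary$uniq == "multi"), 1L)
  expect_true(all(res$summary$n_best >= 1L))
})

test_that("the element model keeps identical LTRs and exact length bookkeeping", {
  elt <- build_etn(847, 6834, seed = 7)
  expect_identical(te_length(elt), 8528L)
  expect_identical(nchar(te_sequence(elt)), 8528L)
  expect_identical(substr(te_sequence(elt), 1, 847),
                   substr(te_sequence(elt), 847 + 6834 + 1, 8528))

  tiny <- build_etn(1, 1, seed = 0)
  expect_identical(te_length(tiny), 3L)
  expect_error(build_etn(0, 10), "positive")
})

test_that("insert_element duplicates the target site and loses no reference base", {
  region <- build_reference(2000, 0, seed = 2)
  elt <- build_etn(50, 120, seed = 3)
  mut <- insert_element(region, elt, 1000, tsd_length = 6)
  hap <- mut$haplotype
  expect_identical(nchar(hap), 2000L + te_length(elt) + 6L)

  # the 6 bases flanking the element on both sides are identical
  p0 <- 999L
  left_flank <- substr(hap, p0 + 1L, p0 + 6L)
  right_flank <- substr(hap, p0 + 6L + te_length(elt) + 1L,
                        p0 + 6L + te_length(elt) + 6L)
  expect_identical(left_flank, right_flank)
  expect_identical(left_flank, substr(region$sequence, 1000, 1005))

  # removing element + one TSD copy reconstructs the reference exactly
  rebuilt <- paste0(substr(hap, 1, p0 + 6L),
                    substr(hap, p0 + 6L + te_length(elt) + 6L + 1L,
                           nchar(hap)))
  expect_identical(rebuilt, region$sequence)

  expect_error(insert_element(region, elt, 1999, tsd_length = 6),
               "out of range")
})

test_that("length bookkeeping is exact over many position/TSD combinations", {
  region <- build_reference(1500, 0, seed = 4)
  elt <- build_etn(20, 55, seed = 5)
  set.seed(42)
  for (i in 1:25) {
    tsd <- sample(0:12, 1)
    pos <- sample.int(1500 - tsd, 1)
    ori <- sample(c("+", "-"), 1)
    mut <- insert_element(region, elt, pos, tsd, ori)
    expect_identical(nchar(mut$haplotype), 1500L + te_length(elt) + tsd)
    p0 <- pos - 1L
    rebuilt <- paste0(substr(mut$haplotype, 1, p0 + tsd),
                      substr(mut$haplotype,
                             p0 + tsd + te_length(elt) + tsd + 1L,
                             nchar(mut$haplotype)))
    expect_identical(rebuilt, region$sequence)
  }
  # degenerate TSD of zero: pure concatenation
  mut0 <- insert_element(region, elt, 700, tsd_length = 0)
  expect_identical(nchar(mut0$haplotype), 1500L + te_length(elt))
})

test_that("error-free wildtype reads are exact substrings of a haplotype strand", {
  region <- build_reference(3000, 0, seed = 6)
  pairs <- simulate_read_pairs(region, "wt", coverage = 5,
                               error_rate = 0, seed = 8)
  for (s in c(pairs$seq1[1:50], pairs$seq2[1:50])) {
    expect_true(grepl(s, region$sequence, fixed = TRUE) ||
                  grepl(rc_chr(s), region$sequence, fixed = TRUE))
  }
})

test_that("pair count tracks coverage * length / (2 * read length)", {
  region <- build_reference(10000, 0, seed = 9)
  pairs <- simulate_read_pairs(region, "wt", coverage = 50,
                               error_rate = 0, seed = 10)
  expect_lt(abs(nrow(pairs) - 50 * 10000 / 72), 0.15 * 50 * 10000 / 72)
})

test_that("identical seeds give byte-identical FASTQ output", {
  region <- fixture_region()
  p1 <- simulate_read_pairs(region, "wt", coverage = 3, seed = 7)
  p2 <- simulate_read_pairs(region, "wt", coverage = 3, seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq_pairs(p1, f1)
  write_fastq_pairs(p2, f2)
  expect_identical(readLines(paste0(f1, "_1.fastq")),
                   readLines(paste0(f2, "_1.fastq")))
  expect_identical(readLines(paste0(f1, "_2.fastq")),
                   readLines(paste0(f2, "_2.fastq")))
  p3 <- simulate_read_pairs(region, "wt", coverage = 3, seed = 8)
  expect_false(identical(p1$seq1, p3$seq1))
})

test_that("capture bias depletes fragments inside repeats", {
  region <- fixture_region()
  mask <- rep(FALSE, nchar(region$sequence))
  red <- IRanges::reduce(GenomicRanges::ranges(region$repeats))
  for (i in seq_along(red)) {
    mask[IRanges::start(red)[i]:IRanges::end(red)[i]] <- TRUE
  }
  pairs <- simulate_read_pairs(region, "wt", coverage = 40,
                               error_rate = 0, seed = 12)
  frac_rep <- vapply(seq_len(nrow(pairs)), function(i) {
    mean(mask[(pairs$frag_start0[i] + 1):(pairs$frag_start0[i] +
                                            pairs$frag_len[i])])
  }, numeric(1))
  # per-base sampling rate inside fully-repeat fragments vs fully-unique
  n_rep_frag <- sum(frac_rep > 0.99)
  n_uniq_frag <- sum(frac_rep < 0.01)
  total_rep <- sum(mask); total_uniq <- sum(!mask)
  expect_lt(n_rep_frag / total_rep, n_uniq_frag / total_uniq)
})

test_that("het truth restricts junction-spanning fragments to the mutant haplotype", {
  pairs <- fixture_pairs("het")
  tr <- attr(pairs, "truth")
  mut <- fixture_mutant()
  # fragment coordinates are haplotype-local; element junctions only exist
  # in mutant space, so junction-overlapping fragments must be hap == mut
  jl <- tr$junction_left0; jr <- tr$junction_right0
  mut_rows <- pairs$hap == "mut"
  spans <- (pairs$frag_start0 < jl &
              pairs$frag_start0 + pairs$frag_len > jl) |
    (pairs$frag_start0 < jr & pairs$frag_start0 + pairs$frag_len > jr)
  expect_gt(sum(spans & mut_rows), 0)
  # and no wildtype-haplotype read can contain a junction-crossing sequence
  junction_kmer <- substr(mut$haplotype, jl - 7L, jl + 8L)
  ref_reads <- c(pairs$seq1[!mut_rows], pairs$seq2[!mut_rows])
  expect_false(any(grepl(junction_kmer, ref_reads, fixed = TRUE)))
  expect_false(any(grepl(rc_chr(junction_kmer), ref_reads, fixed = TRUE)))
})

test_that("fastq round trip preserves sequences and qualities", {
  pairs <- fixture_pairs("het")[1:100, ]
  pre <- tempfile()
  write_fastq_pairs(pairs, pre)
  back <- read_fastq_pairs(paste0(pre, "_1.fastq"), paste0(pre, "_2.fastq"))
  expect_identical(back$seq1, pairs$seq1)
  expect_identical(back$seq2, pairs$seq2)
  expect_identical(back$qual2, pairs$qual2)
})

test_that("repeat annotations survive a BED round trip", {
  region <- fixture_region()
  f <- tempfile(fileext = ".bed")
  write_repeats_bed(region, f)
  gr <- read_repeats_bed(f)
  expect_identical(length(gr), length(region$repeats))
  expect_identical(GenomicRanges::start(gr),
                   GenomicRanges::start(region$repeats))
  expect_identical(as.character(gr$family),
                   as.character(region$repeats$family))
})
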