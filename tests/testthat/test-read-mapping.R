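test_that("exact unique-region copies map uniquely at the truth position", {
  region <- fixture_region()
  site <- choose_insertion_site(region)  # guaranteed unique stretch
  read <- substr(region$sequence, site, site + 35L)
  res <- align_reads(read, region)
  expect_identical(res$summary$uniq, "unique")
  expect_identical(res$summary$pos0, site - 1L)
  expect_identical(res$summary$strand, "+")
  expect_identical(res$summary$nm, 0L)
})

test_that("reads from identical LTR copies are multi-mapping", {
  elt <- fixture_element()
  mut <- fixture_mutant()
  read <- substr(elt$ltr_sequence, 100, 135)
  res <- align_reads(read, mut$haplotype)
  expect_identical(res$summary$uniq, "multi")
  expect_gte(nrow(res$hits), 2L)
})

test_that("mostly-N reads are returned unmapped", {
  region <- fixture_region()
  res <- align_reads(strrep("N", 36), region)
  expect_identical(res$summary$uniq, "unmapped")
  read <- substr(region$sequence, 50, 85)
  substr(read, 1, 9) <- "NNNNNNNNN"  # 25% N
  expect_identical(align_reads(read, region)$summary$uniq, "unmapped")
})

test_that("hit sets equal the exhaustive Hamming oracle on random reads", {
  set.seed(101)
  ref <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  reads <- character(0)
  for (i in 1:40) {
    p <- sample.int(3000 - 35, 1)
    r <- substr(ref, p, p + 35L)
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      rc <- strsplit(r, "")[[1]]
      at <- sample.int(36, nmut)
      rc[at] <- sample(c("A", "C", "G", "T"), nmut, TRUE)
      r <- paste(rc, collapse = "")
    }
    if (runif(1) < 0.5) r <- rc_chr(r)
    reads <- c(reads, r)
  }
  reads <- c(reads, replicate(20, random_read()))
  res <- align_reads(reads, ref, max_mismatch = 2L)
  for (i in seq_along(reads)) {
    got <- res$hits[res$hits$read == i, c("pos0", "strand", "nm")]
    got <- got[order(got$nm, got$pos0, got$strand), , drop = FALSE]
    want <- oracle_scan(reads[i], ref, 2L)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("aligning a reverse complement mirrors coordinates and strand", {
  region <- fixture_region()
  set.seed(7)
  for (i in 1:10) {
    p <- sample.int(nchar(region$sequence) - 35, 1)
    r <- substr(region$sequence, p, p + 35L)
    fwd <- align_reads(r, region)$hits
    rev <- align_reads(rc_chr(r), region)$hits
    expect_identical(fwd$pos0, rev$pos0)
    expect_identical(fwd$nm, rev$nm)
    expect_identical(fwd$strand, chartr("+-", "-+", rev$strand))
  }
})

test_that("pair classification is total and matches the definitions", {
  mk <- function(uniq, pos0, strand, len = 36L) {
    data.frame(qname = "p1", mate = NA_integer_, rname = "r",
               pos0 = pos0, strand = strand, nm = 0L, uniq = uniq,
               seq = strrep("A", len), qual = strrep("I", len),
               stringsAsFactors = FALSE)
  }
  pair <- function(r1, r2) {
    r1$mate <- 1L; r2$mate <- 2L
    classify_pair(r1, r2, frag_bounds = c(150, 500))
  }
  expect_identical(pair(mk("unique", 1000L, "+"),
                        mk("unique", 1264L, "-")), "PROPER")
  expect_identical(pair(mk("unique", 1000L, "+"),
                        mk("unmapped", NA_integer_, NA_character_)), "OEA")
  expect_identical(pair(mk("unique", 1000L, "+"),
                        mk("multi", 1264L, "-")), "OEA")
  expect_identical(pair(mk("unmapped", NA_integer_, NA_character_),
                        mk("unmapped", NA_integer_, NA_character_)),
                   "BOTH_UNMAPPED")
  # same strand: discordant
  expect_identical(pair(mk("unique", 1000L, "+"),
                        mk("unique", 1264L, "+")), "DISCORDANT_OTHER")
  # fragment far beyond bounds: discordant
  expect_identical(pair(mk("unique", 1000L, "+"),
                        mk("unique", 3000L, "-")), "DISCORDANT_OTHER")
  expect_error(pair(mk("unique", 1L, "+"),
                    transform(mk("unique", 50L, "-"), qname = "p2")),
               "different pairs")
})

test_that("every simulated pair gets exactly one class; clean wildtype data is nearly all PROPER", {
  region <- build_reference(10000, 0, seed = 31)  # uniform unique reference
  pairs <- simulate_read_pairs(region, "wt", coverage = 20,
                               error_rate = 0, seed = 32)
  aln <- align_pairs(pairs, region)
  classes <- classify_pairs(aln)
  expect_identical(nrow(classes), nrow(pairs))
  expect_true(all(classes$class %in%
                    c("PROPER", "OEA", "BOTH_UNMAPPED", "DISCORDANT_OTHER")))
  expect_gte(mean(classes$class == "PROPER"), 0.95)
})

test_that("SAM round trip reproduces records exactly, including POS convention", {
  region <- fixture_region()
  pairs <- fixture_pairs("het")[1:500, ]
  aln <- align_pairs(pairs, region)
  f <- tempfile(fileext = ".sam")
  write_sam(aln, region, f)

  # internal start 0 serializes as POS 1
  first_mapped <- aln[!is.na(aln$pos0), ][1, ]
  ln <- grep(paste0("^", first_mapped$qname, "\t"), readLines(f),
             value = TRUE)
  pos_field <- as.integer(vapply(strsplit(ln, "\t"), `[[`, "", 4))
  expect_true((first_mapped$pos0 + 1L) %in% pos_field)

  back <- read_sam(f)
  key <- function(d) d[order(d$qname, d$mate),
                       c("qname", "mate", "pos0", "strand", "nm", "uniq",
                         "seq", "qual")]
  a <- key(aln); b <- key(back)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)

  # second round trip is idempotent
  f2 <- tempfile(fileext = ".sam")
  write_sam(back, region, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("written SAM is accepted by an independent parser", {
  skip_if_not_installed("Rsamtools")
  region <- fixture_region()
  pairs <- fixture_pairs("het")[1:1000, ]
  aln <- align_pairs(pairs, region)
  f <- tempfile(fileext = ".sam")
  write_sam(aln, region, f)
  bam <- Rsamtools::asBam(f, tempfile(), overwrite = TRUE)
  sb <- Rsamtools::scanBam(bam)[[1]]
  expect_identical(length(sb$qname), nrow(aln))
  mapped <- !bitwAnd(sb$flag, 4L)
  expect_identical(sum(mapped), sum(aln$uniq != "unmapped"))
  got <- sort(sb$pos[mapped])
  want <- sort(aln$pos0[!is.na(aln$pos0)] + 1L)
  expect_identical(got, want)
})

test_that("malformed SAM lines are reported with their line numbers", {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "good\t77\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII",
               "short\tline"), f)
  expect_error(read_sam(f), "3")
})
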