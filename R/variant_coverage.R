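#' VAF-threshold variant scan, coverage statistics, tandem-repeat counting
#'
#' Per-base pileups over uniquely mapped reads support a simple
#' variant-allele-fraction (VAF) genotype caller with the two presets used
#' for heterozygous discovery material -- an initial 40% threshold and a
#' relaxed 25%/75% pass -- plus descriptive coverage statistics and
#' exact tandem-repeat copy counting for microsatellite markers.
#'
#' @name variant_and_coverage
NULL

BASES <- c("A", "C", "G", "T", "N")

#' Per-base pileup over uniquely mapped records
#'
#' Only unique-class mapped records contribute. The aligner is ungapped, so
#' every read covers a contiguous reference window; counts at a column
#' always sum to its depth.
#'
#' @param aln alignment record table.
#' @param region a `GenomeRegion`.
#' @return integer matrix with rows A/C/G/T/N and one column per reference
#'   position (0-based position `i` in column `i + 1`).
#' @export
pileup_counts <- function(aln, region) {
  L <- nchar(region$sequence)
  counts <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(BASES, NULL))
  sub <- aln[aln$uniq == "unique" & !is.na(aln$pos0), , drop = FALSE]
  if (nrow(sub) == 0L) return(counts)
  if (!all(sub$rname == region$name)) {
    stop(sprintf("alignment reference name(s) %s do not match region '%s'",
                 paste(unique(setdiff(sub$rname, region$name)),
                       collapse = ", "),
                 region$name))
  }
  oriented <- ifelse(sub$strand == "-", revcomp(sub$seq), sub$seq)
  chars <- strsplit(oriented, "")
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    seq.int(sub$pos0[i], length.out = lens[i])
  }), use.names = FALSE)
  base_i <- match(flat, BASES)
  base_i[is.na(base_i)] <- 5L
  ok <- pos >= 0L & pos < L
  idx <- pos[ok] * 5L + base_i[ok]
  tab <- tabulate(idx, nbins = 5L * L)
  counts[] <- tab
  counts
}

#' Call variants from a pileup by VAF thresholds
#'
#' At each column the dominant non-reference base defines the VAF. A column
#' is called heterozygous when `het_min <= VAF < hom_min` and homozygous
#' alternate when `VAF >= hom_min`; columns below `min_depth` are skipped.
#' Presets: `"initial"` sets `het_min = 0.40`, `"relaxed"` sets
#' `het_min = 0.25`, both with `hom_min = 0.75`. Columns where a second
#' non-reference base also reaches `het_min` are flagged multi-allelic.
#'
#' @param aln alignment record table (or a precomputed pileup via
#'   `counts`).
#' @param region a `GenomeRegion`.
#' @param het_min heterozygous VAF floor.
#' @param hom_min homozygous-alternate VAF floor.
#' @param min_depth minimum depth for a callable column.
#' @param preset `"initial"` or `"relaxed"` (overrides `het_min`).
#' @param counts optional pileup matrix from [pileup_counts()].
#' @return data.frame of `VariantCall`s: `region`, `position` (1-based),
#'   `ref`, `alt`, `vaf`, `depth`, `genotype`, `multiallelic`.
#' @export
pileup_and_call <- function(aln, region, het_min = 0.40, hom_min = 0.75,
                            min_depth = 8L, preset = NULL, counts = NULL) {
  if (!is.null(preset)) {
    het_min <- switch(match.arg(preset, c("initial", "relaxed")),
                      initial = 0.40, relaxed = 0.25)
  }
  if (het_min >= hom_min) stop("het_min must be < hom_min")
  if (is.null(counts)) counts <- pileup_counts(aln, region)
  acgt <- counts[1:4, , drop = FALSE]
  depth <- colSums(counts)
  refbase <- strsplit(region$sequence, "")[[1]]
  ref_i <- match(refbase, BASES[1:4])
  nonref <- acgt
  nonref[cbind(ref_i, seq_along(ref_i))] <- 0L
  top_i <- max.col(t(nonref), ties.method = "first")
  top_n <- nonref[cbind(top_i, seq_along(ref_i))]
  second <- nonref
  second[cbind(top_i, seq_along(ref_i))] <- 0L
  second_n <- apply(second, 2L, max)
  vaf <- ifelse(depth > 0, top_n / depth, 0)
  callable <- depth >= min_depth & vaf >= het_min
  pos <- which(callable)
  if (length(pos) == 0L) {
    return(data.frame(
      region = character(), position = integer(), ref = character(),
      alt = character(), vaf = numeric(), depth = integer(),
      genotype = character(), multiallelic = logical(),
      stringsAsFactors = FALSE
    ))
  }
  data.frame(
    region = region$name,
    position = pos,
    ref = refbase[pos],
    alt = BASES[top_i[pos]],
    vaf = vaf[pos],
    depth = as.integer(depth[pos]),
    genotype = ifelse(vaf[pos] >= hom_min, "hom_alt", "het"),
    multiallelic = second_n[pos] / depth[pos] >= het_min,
    stringsAsFactors = FALSE
  )
}

#' Coverage statistics over a target interval
#'
#' @param aln alignment record table.
#' @param region a `GenomeRegion`.
#' @param interval 1-based closed target interval `c(lo, hi)`; default the
#'   whole region.
#' @param classes optional pair classification table; when supplied, the
#'   fraction of pairs that are PROPER with fragments overlapping the
#'   interval is reported.
#' @param bin_width depth-histogram bin width.
#' @return list with `covered_bases` (depth >= 1), `fraction_covered`,
#'   `mean_depth` (over the whole interval), `proper_pair_fraction`
#'   (`NA` without `classes`), `histogram` (data.frame `depth_lo`,
#'   `depth_hi`, `n_positions`), and the per-position `depth` vector.
#' @export
coverage_stats <- function(aln, region, interval = NULL, classes = NULL,
                           bin_width = 10L) {
  L <- nchar(region$sequence)
  if (is.null(interval)) interval <- c(1L, L)
  if (interval[1] < 1L || interval[2] > L || interval[1] > interval[2]) {
    stop("empty or out-of-range interval")
  }
  depth <- colSums(pileup_counts(aln, region))[interval[1]:interval[2]]
  n <- length(depth)
  covered <- sum(depth >= 1L)
  brk <- seq(0L, max(depth, bin_width) + bin_width, by = bin_width)
  hist_n <- tabulate(findInterval(depth, brk, left.open = FALSE),
                     nbins = length(brk) - 1L)
  histogram <- data.frame(
    depth_lo = brk[-length(brk)], depth_hi = brk[-1] - 1L,
    n_positions = hist_n
  )
  proper_frac <- NA_real_
  if (!is.null(classes) && nrow(classes)) {
    on_target <- classes$class == "PROPER" &
      !is.na(classes$frag_start0) &
      classes$frag_end0 >= interval[1] - 1L &
      classes$frag_start0 <= interval[2] - 1L
    proper_frac <- mean(on_target)
  }
  list(
    covered_bases = covered,
    fraction_covered = covered / n,
    mean_depth = mean(depth),
    proper_pair_fraction = proper_frac,
    histogram = histogram,
    depth = depth
  )
}

#' Write a coverage summary and depth histogram as TSV
#'
#' @param stats result of [coverage_stats()].
#' @param summary_tsv,histogram_tsv output paths (`NULL` to skip).
#' @export
write_coverage_report <- function(stats, summary_tsv = NULL,
                                  histogram_tsv = NULL) {
  if (!is.null(summary_tsv)) {
    df <- data.frame(
      metric = c("covered_bases", "fraction_covered", "mean_depth",
                 "proper_pair_fraction"),
      value = c(stats$covered_bases, stats$fraction_covered,
                stats$mean_depth, stats$proper_pair_fraction)
    )
    write.table(df, summary_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(histogram_tsv)) {
    write.table(stats$histogram, histogram_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(stats)
}

#' Write covered intervals (depth >= 1) as BED
#'
#' @param stats result of [coverage_stats()].
#' @param region the `GenomeRegion` the stats were computed on.
#' @param path BED output file.
#' @param min_depth minimum depth for a base to count as covered.
#' @export
write_covered_bed <- function(stats, region, path, min_depth = 1L) {
  covered <- stats$depth >= min_depth
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  gr <- GenomicRanges::GRanges(
    region$name,
    IRanges::IRanges(start = starts[keep], end = ends[keep])
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Longest exact tandem run of a motif
#'
#' Counts head-to-tail copies of `motif`; the leftmost maximal run wins
#' ties. Used for microsatellite genotyping (e.g. the number of TATC
#' copies distinguishing mutant from wildtype alleles).
#'
#' @param sequence DNA string.
#' @param motif repeat unit (length >= 1).
#' @return list with `copies` (0 when the motif is absent) and `start`
#'   (1-based start of the run, `NA` when absent).
#' @export
count_tandem_repeats <- function(sequence, motif) {
  if (nchar(motif) < 1L) stop("empty motif")
  sequence <- toupper(sequence); motif <- toupper(motif)
  pat <- paste0("(?:", gsub("([^ACGTN])", "\\\\\\1", motif), ")+")
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(copies = 0L, start = NA_integer_))
  lens <- attr(m, "match.length")
  copies <- lens %/% nchar(motif)
  best <- which.max(copies)  # leftmost maximum
  list(copies = copies[best], start = as.integer(m[best]))
}

#' Write variant calls as a VCF-like TSV
#'
#' @param calls data.frame from [pileup_and_call()].
#' @param path output file (columns CHROM, POS, REF, ALT, VAF, DEPTH, GT).
#' @export
write_variant_report <- function(calls, path) {
  out <- data.frame(
    CHROM = calls$region, POS = calls$position, REF = calls$ref,
    ALT = calls$alt, VAF = calls$vaf, DEPTH = calls$depth,
    GT = calls$genotype
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
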