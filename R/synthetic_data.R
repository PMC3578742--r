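#' Reference regions, retroelement models, and simulated capture sequencing
#'
#' The simulator emulates the statistical structure of a targeted-capture
#' short-read experiment over a repeat-rich genomic interval: a reference
#' region about half of which is annotated repeat copies, an
#' LTR-internal-LTR retroelement inserted with a target-site duplication
#' (TSD), and 36-bp inward-facing paired-end reads from ~300-bp fragments
#' whose capture probability is depleted inside repeats (probes cover only
#' unique sequence).
#'
#' @name synthetic_data
NULL

#' Construct a GenomeRegion
#'
#' A named reference sequence plus repeat annotations (a [GenomicRanges::GRanges]
#' with a `family` metadata column; 1-based closed coordinates as usual for
#' GRanges).
#'
#' @param name region name (used as the SAM/BED sequence name).
#' @param sequence DNA string over A/C/G/T.
#' @param repeats `GRanges` of annotated repeat copies, or `NULL` for none.
#' @return an object of class `GenomeRegion`.
#' @export
GenomeRegion <- function(name, sequence, repeats = NULL) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("sequence length must be > 0")
  if (grepl("[^ACGT]", sequence)) stop("sequence must be over {A,C,G,T}")
  if (is.null(repeats)) {
    repeats <- GenomicRanges::GRanges(
      seqnames = character(), ranges = IRanges::IRanges(),
      strand = character(), family = character()
    )
  }
  if (!is(repeats, "GRanges")) stop("repeats must be a GRanges or NULL")
  if (is.null(repeats$family)) repeats$family <- rep("repeat", length(repeats))
  if (length(repeats) &&
      (min(GenomicRanges::start(repeats)) < 1L ||
       max(GenomicRanges::end(repeats)) > nchar(sequence))) {
    stop("repeat annotations fall outside the region")
  }
  structure(
    list(name = name, sequence = sequence, repeats = repeats),
    class = "GenomeRegion"
  )
}

#' @export
print.GenomeRegion <- function(x, ...) {
  cat(sprintf(
    "GenomeRegion '%s': %d bp, %d repeat annotations (%.1f%% of bases)\n",
    x$name, nchar(x$sequence), length(x$repeats), 100 * repeat_fraction(x)
  ))
  invisible(x)
}

#' Fraction of region bases covered by repeat annotations
#'
#' @param region a `GenomeRegion`.
#' @return real in \[0, 1\].
#' @export
repeat_fraction <- function(region) {
  if (length(region$repeats) == 0L) return(0)
  covered <- sum(IRanges::width(IRanges::reduce(
    GenomicRanges::ranges(region$repeats)
  )))
  covered / nchar(region$sequence)
}

# logical mask along the region: TRUE where a base is inside an annotation
repeat_mask <- function(region) {
  mask <- logical(nchar(region$sequence))
  if (length(region$repeats)) {
    red <- IRanges::reduce(GenomicRanges::ranges(region$repeats))
    for (i in seq_along(red)) {
      mask[IRanges::start(red)[i]:IRanges::end(red)[i]] <- TRUE
    }
  }
  mask
}

#' Build a synthetic repeat-rich reference region
#'
#' Generates `n_families` random consensus sequences and plants diverged
#' copies (per-copy substitution rate `divergence`) at non-overlapping
#' positions until about `repeat_fraction` of the region is annotated
#' repeat. Multiple near-identical copies per family make genuine
#' multi-mapping occur, as in real repeat-rich intervals.
#'
#' @param length region length in bp (>= 1000 when `repeat_fraction` > 0).
#' @param repeat_fraction target fraction of annotated repeat bases, in \[0,1\].
#' @param n_families number of repeat families.
#' @param seed integer seed; output is deterministic given the seed.
#' @param divergence per-copy substitution rate applied to each planted copy.
#' @param consensus_lengths optional integer vector (recycled over families)
#'   of family consensus lengths; default lengths between 150 and 500 bp.
#' @param name region name.
#' @return a `GenomeRegion`; its annotated-base fraction is within ~10% of
#'   the request for feasible inputs.
#' @export
build_reference <- function(length, repeat_fraction, n_families = 3L,
                            seed = 1L, divergence = 0.02,
                            consensus_lengths = NULL, name = "region") {
  if (length < 1L) stop("length must be positive")
  if (repeat_fraction < 0 || repeat_fraction > 1) {
    stop("repeat_fraction must be in [0, 1]")
  }
  if (repeat_fraction > 0 && length < 1000L) {
    stop("length must be >= 1000 for nonzero repeat_fraction")
  }
  if (n_families < 1L) stop("n_families must be positive")
  set.seed(derive_seed(seed, 11L))

  base <- strsplit(random_dna(length), "")[[1]]
  if (repeat_fraction == 0) {
    return(GenomeRegion(name, paste(base, collapse = "")))
  }

  if (is.null(consensus_lengths)) {
    consensus_lengths <- round(seq(150, 500, length.out = max(n_families, 2L)))
    consensus_lengths <- consensus_lengths[seq_len(n_families)]
  }
  consensus_lengths <- rep_len(as.integer(consensus_lengths), n_families)
  consensus_lengths <- pmin(consensus_lengths, max(50L, length %/% 4L))
  consensus <- vapply(consensus_lengths, random_dna, character(1))
  fam_names <- paste0("FAM", seq_len(n_families))

  target <- round(repeat_fraction * length)
  occupied <- logical(length)
  placed <- 0L
  starts <- integer(); ends <- integer(); fams <- character()
  strands <- character()
  attempts <- 0L
  while (placed < target && attempts < 200L * n_families) {
    attempts <- attempts + 1L
    f <- sample.int(n_families, 1L)
    w <- min(consensus_lengths[f], target - placed + 25L)
    if (w < 50L) w <- min(50L, consensus_lengths[f])
    if (w > length) next
    s <- sample.int(length - w + 1L, 1L)
    if (any(occupied[s:(s + w - 1L)])) next
    strand <- sample(c("+", "-"), 1L)
    copy <- substr(consensus[f], 1L, w)
    if (strand == "-") copy <- revcomp(copy)
    cc <- strsplit(copy, "")[[1]]
    nmut <- rbinom(1L, w, divergence)
    if (nmut > 0L) {
      at <- sample.int(w, nmut)
      cc[at] <- vapply(cc[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
    base[s:(s + w - 1L)] <- cc
    occupied[s:(s + w - 1L)] <- TRUE
    placed <- placed + w
    starts <- c(starts, s); ends <- c(ends, s + w - 1L)
    fams <- c(fams, fam_names[f]); strands <- c(strands, strand)
  }
  repeats <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands, family = fams
  )
  region <- GenomeRegion(name, paste(base, collapse = ""), repeats)
  attr(region, "consensus") <- setNames(consensus, fam_names)
  region
}

#' Construct an LTR-internal-LTR retroelement
#'
#' The element model mirrors an ETn-class endogenous retrovirus: two
#' identical long terminal repeats (LTRs) flanking an internal sequence,
#' total length `2 * ltr_len + internal_len`.
#'
#' @param ltr_len LTR length in bp (847 for the ETn studied here).
#' @param internal_len internal sequence length in bp (6,834 for that ETn).
#' @param seed integer seed for the random sequences.
#' @param family family label.
#' @return an object of class `TEElement` with fields `family`,
#'   `ltr_sequence`, `internal_sequence`.
#' @export
build_etn <- function(ltr_len = 847L, internal_len = 6834L, seed = 1L,
                      family = "ETn") {
  if (ltr_len < 1L || internal_len < 1L) stop("lengths must be positive")
  set.seed(derive_seed(seed, 23L))
  structure(
    list(
      family = family,
      ltr_sequence = random_dna(ltr_len),
      internal_sequence = random_dna(internal_len)
    ),
    class = "TEElement"
  )
}

#' Full element sequence (5' LTR + internal + identical 3' LTR)
#' @param element a `TEElement`.
#' @return DNA string.
#' @export
te_sequence <- function(element) {
  paste0(element$ltr_sequence, element$internal_sequence,
         element$ltr_sequence)
}

#' Total element length in bp
#' @param element a `TEElement`.
#' @export
te_length <- function(element) {
  2L * nchar(element$ltr_sequence) + nchar(element$internal_sequence)
}

#' @export
print.TEElement <- function(x, ...) {
  cat(sprintf("TEElement %s: LTR %d bp x2 + internal %d bp = %d bp\n",
              x$family, nchar(x$ltr_sequence), nchar(x$internal_sequence),
              te_length(x)))
  invisible(x)
}

#' Insert a retroelement into a reference with a target-site duplication
#'
#' `position` is the 1-based coordinate of the first duplicated base; the
#' `tsd_length` bases starting there appear immediately before and after the
#' element in the mutant haplotype, so no reference base is lost:
#' `mutant = ref[1..position+tsd-1] element ref[position..end]`.
#'
#' @param region a `GenomeRegion`.
#' @param element a `TEElement`.
#' @param position 1-based coordinate of the first duplicated base.
#' @param tsd_length target-site duplication length in bp (6 is typical of
#'   ETn integration).
#' @param orientation `"+"` to insert the element sequence as-is, `"-"` for
#'   its reverse complement.
#' @return a list with `haplotype` (mutant DNA string) and `truth` (a
#'   `SampleTruth` list: genotype placeholder, `insertion_position`,
#'   `tsd_length`, `family`, `orientation`, plus the 0-based mutant-space
#'   junction coordinates `junction_left0` / `junction_right0` of the two
#'   reference/element boundaries).
#' @export
insert_element <- function(region, element, position, tsd_length = 6L,
                           orientation = "+") {
  L <- nchar(region$sequence)
  position <- as.integer(position)
  tsd_length <- as.integer(tsd_length)
  if (tsd_length < 0L) stop("tsd_length must be >= 0")
  if (position < 1L || position + tsd_length - 1L > L) {
    stop("position out of range")
  }
  if (!orientation %in% c("+", "-")) stop("orientation must be '+' or '-'")
  elt <- te_sequence(element)
  if (orientation == "-") elt <- revcomp(elt)
  p0 <- position - 1L # 0-based first duplicated base
  left <- substr(region$sequence, 1L, p0 + tsd_length)
  right <- substr(region$sequence, position, L)
  haplotype <- paste0(left, elt, right)
  stopifnot(nchar(haplotype) == L + nchar(elt) + tsd_length)
  truth <- structure(
    list(
      genotype = NA_character_,
      insertion_position = position,
      tsd_length = tsd_length,
      family = element$family,
      orientation = orientation,
      element_length = nchar(elt),
      junction_left0 = p0 + tsd_length,
      junction_right0 = p0 + tsd_length + nchar(elt)
    ),
    class = "SampleTruth"
  )
  list(haplotype = haplotype, truth = truth)
}

# per-haplotype repeat mask used for capture bias; the inserted element
# itself counts as repeat (capture probes exclude repetitive sequence)
haplotype_masks <- function(region, mutant = NULL) {
  ref_mask <- repeat_mask(region)
  masks <- list(ref = ref_mask)
  if (!is.null(mutant)) {
    tr <- mutant$truth
    p0 <- tr$insertion_position - 1L
    ins_len <- tr$element_length + tr$tsd_length
    mut_mask <- c(
      ref_mask[seq_len(p0 + tr$tsd_length)],
      rep(TRUE, tr$element_length),
      ref_mask[seq.int(p0 + 1L, length(ref_mask))]
    )
    stopifnot(length(mut_mask) == nchar(mutant$haplotype))
    masks$mut <- mut_mask
  }
  masks
}

#' Simulate targeted-capture paired-end reads with known truth
#'
#' Draws ~`coverage * mean(haplotype length) / (2 * read_len)` inward-facing
#' FR read pairs from fragments of length ~ Normal(`frag_mean`, `frag_sd`)
#' truncated to \[2*read_len, 2*frag_mean\]. Capture is emulated by accepting
#' each proposed fragment with probability `max(capture_eps, unique-overlap
#' fraction)`, depleting fragments inside repeats (and inside an inserted
#' element) as hybridization probes restricted to unique sequence would.
#' Heterozygous samples draw fragments from both haplotypes with equal prior
#' before capture bias. Base-call errors are uniform substitutions.
#'
#' @param region a `GenomeRegion` (wildtype haplotype).
#' @param genotype `"wt"`, `"het"` or `"hom"`.
#' @param mutant result of [insert_element()]; required unless `genotype`
#'   is `"wt"`.
#' @param coverage target mean depth (x).
#' @param read_len read length in bp.
#' @param frag_mean,frag_sd fragment length distribution (bp).
#' @param error_rate per-base substitution rate in \[0,1\].
#' @param capture_eps floor on the capture acceptance probability.
#' @param capture set `FALSE` to disable capture bias entirely.
#' @param seed integer master seed; byte-identical output for equal seeds.
#' @param sample_name sample identifier used in read names and truth table.
#' @return a `data.frame` of read pairs (one row per pair) with columns
#'   `pair_id`, `seq1`, `qual1`, `seq2`, `qual2`, `hap` (`"ref"`/`"mut"`),
#'   `frag_start0`, `frag_len`, `frag_strand`, and attributes `truth`
#'   (sample-level truth list) and `params`.
#' @export
simulate_read_pairs <- function(region, genotype = c("wt", "het", "hom"),
                                mutant = NULL, coverage = 50,
                                read_len = 36L, frag_mean = 300,
                                frag_sd = 30, error_rate = 0.005,
                                capture_eps = 0.05, capture = TRUE,
                                seed = 1L, sample_name = genotype) {
  genotype <- match.arg(genotype)
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (frag_mean < 2 * read_len) stop("frag_mean must be >= 2 * read_len")
  if (genotype != "wt" && is.null(mutant)) {
    stop("mutant haplotype required for het/hom samples")
  }
  sample_name <- sample_name[1]

  haps <- switch(genotype,
    wt = c(ref = region$sequence, ref2 = region$sequence),
    het = c(ref = region$sequence, mut = mutant$haplotype),
    hom = c(mut = mutant$haplotype, mut2 = mutant$haplotype)
  )
  hap_label <- sub("2$", "", names(haps))
  masks <- haplotype_masks(region, mutant)
  mask_cum <- lapply(masks, function(m) c(0, cumsum(m)))
  hap_len <- nchar(haps)

  n_pairs <- round(coverage * mean(hap_len) / (2 * read_len))
  set.seed(derive_seed(seed, 101L))

  frag_lo <- 2L * as.integer(read_len)
  frag_hi <- as.integer(2 * frag_mean)

  out_hap <- integer(0); out_start <- integer(0); out_len <- integer(0)
  got <- 0L
  while (got < n_pairs) {
    m <- max(1000L, 2L * (n_pairs - got))
    hap_i <- sample.int(2L, m, replace = TRUE)
    fl <- as.integer(round(rnorm(m, frag_mean, frag_sd)))
    fl <- pmin(pmax(fl, frag_lo), frag_hi)
    maxstart <- hap_len[hap_i] - fl + 1L
    ok <- maxstart >= 1L
    st <- ifelse(ok, 1L + as.integer(floor(runif(m) * maxstart)), 1L)
    if (capture) {
      rep_bases <- vapply(seq_len(m), function(j) {
        if (!ok[j]) return(0)
        cs <- mask_cum[[hap_label[hap_i[j]]]]
        cs[st[j] + fl[j]] - cs[st[j]]
      }, numeric(1))
      uniq_frac <- 1 - rep_bases / fl
      acc <- ok & (runif(m) < pmax(capture_eps, uniq_frac))
    } else {
      acc <- ok
    }
    keep <- which(acc)
    if (length(keep)) {
      keep <- keep[seq_len(min(length(keep), n_pairs - got))]
      out_hap <- c(out_hap, hap_i[keep])
      out_start <- c(out_start, st[keep])
      out_len <- c(out_len, fl[keep])
      got <- got + length(keep)
    }
  }

  frag_strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  fwd <- substring(haps[out_hap], out_start, out_start + read_len - 1L)
  rev <- revcomp(substring(haps[out_hap], out_start + out_len - read_len,
                           out_start + out_len - 1L))
  seq1 <- ifelse(frag_strand == "+", fwd, rev)
  seq2 <- ifelse(frag_strand == "+", rev, fwd)
  if (error_rate > 0) {
    seq1 <- add_errors(seq1, error_rate)
    seq2 <- add_errors(seq2, error_rate)
  }
  qual <- strrep("I", read_len)

  pairs <- data.frame(
    pair_id = sprintf("%s_p%06d", sample_name, seq_len(n_pairs)),
    seq1 = seq1, qual1 = qual, seq2 = seq2, qual2 = qual,
    hap = hap_label[out_hap],
    frag_start0 = out_start - 1L, frag_len = out_len,
    frag_strand = frag_strand,
    stringsAsFactors = FALSE
  )
  truth <- list(
    sample = sample_name, genotype = genotype,
    insertion_position = if (genotype == "wt") NA_integer_ else
      mutant$truth$insertion_position,
    tsd_length = if (genotype == "wt") NA_integer_ else
      mutant$truth$tsd_length,
    family = if (genotype == "wt") NA_character_ else mutant$truth$family,
    orientation = if (genotype == "wt") NA_character_ else
      mutant$truth$orientation,
    junction_left0 = if (genotype == "wt") NA_integer_ else
      mutant$truth$junction_left0,
    junction_right0 = if (genotype == "wt") NA_integer_ else
      mutant$truth$junction_right0
  )
  attr(pairs, "truth") <- truth
  attr(pairs, "params") <- list(
    coverage = coverage, read_len = as.integer(read_len),
    frag_mean = frag_mean, frag_sd = frag_sd, error_rate = error_rate,
    capture_eps = capture_eps, seed = seed
  )
  pairs
}

# uniform substitution errors applied to a character vector of reads
add_errors <- function(seqs, rate) {
  chars <- strsplit(seqs, "")
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit)) {
    flat[hit] <- vapply(flat[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  vapply(split(flat, rep.int(seq_along(lens), lens)), paste,
         character(1), collapse = "")
}

#' Write simulated pairs as mate FASTQ files
#'
#' @param pairs result of [simulate_read_pairs()].
#' @param prefix output path prefix; `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written (Phred+33).
#' @return the two file paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    sq <- Biostrings::DNAStringSet(pairs[[paste0("seq", m)]])
    names(sq) <- paste0(pairs$pair_id, "/", m)
    qu <- Biostrings::PhredQuality(pairs[[paste0("qual", m)]])
    qsq <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(sq, qu))
    Biostrings::writeQualityScaledXStringSet(qsq, paths[m])
  }
  invisible(paths)
}

#' Read mate FASTQ files back into a pair table
#'
#' @param path1,path2 mate FASTQ files (`/1` and `/2` read-name suffixes
#'   are stripped when pairing).
#' @return a `data.frame` with `pair_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  id1 <- sub("/[12]$", "", names(r1))
  id2 <- sub("/[12]$", "", names(r2))
  if (!identical(id1, id2)) stop("mate files are not in matching order")
  data.frame(
    pair_id = id1,
    seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2)),
    stringsAsFactors = FALSE
  )
}

#' Write a region's repeat annotations as BED
#'
#' 0-based half-open intervals with the family label in the name column.
#' @param region a `GenomeRegion`.
#' @param path output file.
#' @export
write_repeats_bed <- function(region, path) {
  gr <- region$repeats
  if (length(gr)) names(gr) <- gr$family
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read repeat annotations from BED
#'
#' @param path BED file; the name column is taken as the repeat family.
#' @return a `GRanges` with a `family` metadata column.
#' @export
read_repeats_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$family <- if (!is.null(gr$name)) gr$name else rep("repeat", length(gr))
  gr
}
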