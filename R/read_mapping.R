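#' Unique-mapping ungapped alignment of short paired-end reads
#'
#' A deliberately small aligner for 36-bp-era reads on desk-scale
#' references: every position on both strands with Hamming distance up to
#' `max_mismatch` is found via pigeonhole-complete exact k-mer seeding
#' (max_mismatch + 1 non-overlapping seeds per read), so the hit set equals
#' an exhaustive scan. Gapped alignment is unsupported.
#'
#' @name read_mapping
NULL

MAX_N_FRACTION <- 0.20

#' Align reads against a reference, reporting all hits and uniqueness
#'
#' @param seqs character vector of read sequences.
#' @param reference a `GenomeRegion` or a DNA string.
#' @param max_mismatch maximum Hamming distance for a reported hit.
#' @return a list with `hits` (data.frame `read`, `pos0`, `strand`, `nm`,
#'   all hits, best mismatch tier first and leftmost first within a tier)
#'   and `summary` (one row per read: `uniq` class in unique/multi/unmapped,
#'   primary `pos0`, `strand`, `nm`, and `n_best`, the number of best-tier
#'   hits). Reads with more than 20% `N` are returned unmapped.
#' @export
align_reads <- function(seqs, reference, max_mismatch = 2L) {
  refseq <- if (is(reference, "GenomeRegion")) reference$sequence else
    toupper(as.character(reference))
  seqs <- toupper(seqs)
  n <- length(seqs)
  n_frac <- vapply(seqs, function(s) {
    mean(strsplit(s, "")[[1]] == "N")
  }, numeric(1), USE.NAMES = FALSE)
  scanable <- which(n_frac <= MAX_N_FRACTION & nchar(seqs) > 0L)

  hits <- .hamming_scan(seqs[scanable], refseq, as.integer(max_mismatch))
  hits$read <- scanable[hits$read]
  hits <- hits[order(hits$read, hits$nm, hits$pos0), , drop = FALSE]
  rownames(hits) <- NULL

  summary <- data.frame(
    read = seq_len(n), uniq = "unmapped", pos0 = NA_integer_,
    strand = NA_character_, nm = NA_integer_, n_best = 0L,
    stringsAsFactors = FALSE
  )
  if (nrow(hits)) {
    first <- !duplicated(hits$read)
    idx <- hits$read[first]
    summary$pos0[idx] <- hits$pos0[first]
    summary$strand[idx] <- hits$strand[first]
    summary$nm[idx] <- hits$nm[first]
    best_nm <- summary$nm[hits$read]
    nb <- tapply(hits$nm == best_nm, hits$read, sum)
    summary$n_best[as.integer(names(nb))] <- as.integer(nb)
    summary$uniq[idx] <- ifelse(summary$n_best[idx] == 1L, "unique", "multi")
  }
  list(hits = hits, summary = summary)
}

#' Align simulated (or imported) read pairs
#'
#' Produces one alignment record per mate in the layout used throughout the
#' package: internal 0-based starts, uniqueness class, and mismatch count.
#'
#' @param pairs pair table with `pair_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (e.g. from [simulate_read_pairs()] or [read_fastq_pairs()]).
#' @param region a `GenomeRegion`.
#' @param max_mismatch maximum Hamming distance.
#' @return a `data.frame` of `AlignmentRecord`s: `qname`, `mate`, `rname`,
#'   `pos0`, `strand`, `nm`, `uniq`, `seq`, `qual` (unmapped records carry
#'   `NA` coordinates).
#' @export
align_pairs <- function(pairs, region, max_mismatch = 2L) {
  seqs <- c(pairs$seq1, pairs$seq2)
  quals <- c(pairs$qual1, pairs$qual2)
  n <- nrow(pairs)
  res <- align_reads(seqs, region, max_mismatch)$summary
  out <- data.frame(
    qname = rep(pairs$pair_id, 2L),
    mate = rep(1:2, each = n),
    rname = region$name,
    pos0 = res$pos0, strand = res$strand, nm = res$nm, uniq = res$uniq,
    n_best = res$n_best,
    seq = seqs, qual = quals,
    stringsAsFactors = FALSE
  )
  out[order(match(out$qname, pairs$pair_id), out$mate), , drop = FALSE]
}

#' Classify one read pair
#'
#' `PROPER`: both mates unique, opposite strands, inward-facing, inferred
#' fragment length within `frag_bounds`. `OEA` (one-end-anchored): exactly
#' one mate unique, the other unmapped or multi-mapping. `BOTH_UNMAPPED`:
#' neither mate maps. Everything else is `DISCORDANT_OTHER`.
#'
#' @param rec1,rec2 single-row alignment records of the two mates (same
#'   `qname`).
#' @param frag_bounds numeric length-2 inferred-fragment-length bounds (bp).
#' @return one of `"PROPER"`, `"OEA"`, `"BOTH_UNMAPPED"`,
#'   `"DISCORDANT_OTHER"`.
#' @export
classify_pair <- function(rec1, rec2, frag_bounds = c(180, 420)) {
  if (!identical(rec1$qname, rec2$qname)) {
    stop("records belong to different pairs")
  }
  tab <- rbind(as.data.frame(rec1), as.data.frame(rec2))
  classify_pair_table(tab, frag_bounds)$class
}

# vectorized pair classification over a full alignment record table;
# returns one row per pair: qname, class, fragment interval for PROPER pairs
classify_pair_table <- function(aln, frag_bounds = c(180, 420)) {
  a1 <- aln[aln$mate == 1L, , drop = FALSE]
  a2 <- aln[aln$mate == 2L, , drop = FALSE]
  a1 <- a1[order(a1$qname), , drop = FALSE]
  a2 <- a2[order(a2$qname), , drop = FALSE]
  if (!identical(a1$qname, a2$qname)) stop("unpaired alignment records")
  len1 <- nchar(a1$seq); len2 <- nchar(a2$seq)
  u1 <- a1$uniq == "unique"; u2 <- a2$uniq == "unique"
  m1 <- a1$uniq != "unmapped"; m2 <- a2$uniq != "unmapped"

  fwd_start <- ifelse(!is.na(a1$strand) & a1$strand == "+", a1$pos0, a2$pos0)
  rev_end <- ifelse(!is.na(a1$strand) & a1$strand == "-",
                    a1$pos0 + len1, a2$pos0 + len2)
  tlen <- rev_end - fwd_start
  opposite <- !is.na(a1$strand) & !is.na(a2$strand) & a1$strand != a2$strand
  inward <- opposite & !is.na(tlen) & tlen >= pmax(len1, len2)
  proper <- u1 & u2 & inward &
    tlen >= frag_bounds[1] & tlen <= frag_bounds[2]
  oea <- xor(u1, u2)  # exactly one unique; the mate is unmapped or multi
  cls <- ifelse(proper, "PROPER",
         ifelse(oea, "OEA",
         ifelse(!m1 & !m2, "BOTH_UNMAPPED", "DISCORDANT_OTHER")))
  data.frame(
    qname = a1$qname, class = cls,
    frag_start0 = ifelse(proper, fwd_start, NA_integer_),
    frag_end0 = ifelse(proper, rev_end, NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Classify every pair in an alignment table
#'
#' @param aln alignment record table from [align_pairs()].
#' @param frag_bounds inferred-fragment-length bounds; the simulator default
#'   geometry gives `c(300 - 4 * 30, 300 + 4 * 30)`.
#' @return data.frame with one row per pair: `qname`, `class`, and the
#'   fragment interval (`frag_start0`, `frag_end0`, 0-based half-open) for
#'   PROPER pairs.
#' @export
classify_pairs <- function(aln, frag_bounds = c(180, 420)) {
  classify_pair_table(aln, frag_bounds)
}
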