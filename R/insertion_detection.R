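#' Insertion detection from one-end-anchored read pairs
#'
#' The central inference of the package: read pairs in which one end maps
#' uniquely inside the target region while the other end fails to map but
#' matches a repeat consensus library ("one-end-anchored", OEA) are
#' collected, clustered by anchor position on each side of the putative
#' insertion, and turned into insertion calls with breakpoints refined to
#' base resolution from junction-spanning reads, a target-site-duplication
#' (TSD) estimate, zygosity from reference-spanning pairs, and a novelty
#' flag against known repeat annotations.
#'
#' @name insertion_detection
NULL

#' Collect one-end-anchored anchor candidates
#'
#' One candidate per OEA pair whose unique anchor lies in the target
#' interval and whose unmapped/multi mate passed the low-complexity filter
#' and received a repeat-library hit. Side follows the anchor strand:
#' forward anchors sit upstream of the insertion (`left`), reverse anchors
#' downstream (`right`).
#'
#' @param aln alignment record table ([align_pairs()] / [read_sam()]).
#' @param classes pair classification table ([classify_pairs()]).
#' @param repeat_library consensus library ([te_library()] /
#'   [read_repeat_library()]).
#' @param target optional 1-based closed interval `c(lo, hi)` restricting
#'   anchor positions.
#' @param min_identity,min_len,dust_threshold repeat-classification
#'   settings (see [classify_repeats()]).
#' @return data.frame of `AnchorCandidate`s: `qname`, `anchor_start0`,
#'   `anchor_end0`, `anchor_strand`, `side`, `family`, `mate_region`,
#'   `mate_offset`, `mate_strand`, `mate_seq`.
#' @export
collect_oea <- function(aln, classes, repeat_library, target = NULL,
                        min_identity = 0.90, min_len = 20L,
                        dust_threshold = 2.0) {
  oea_q <- classes$qname[classes$class == "OEA"]
  empty <- data.frame(
    qname = character(), anchor_start0 = integer(), anchor_end0 = integer(),
    anchor_strand = character(), side = character(), family = character(),
    mate_region = character(), mate_offset = integer(),
    mate_strand = character(), mate_seq = character(),
    stringsAsFactors = FALSE
  )
  if (length(oea_q) == 0L) return(empty)
  sub <- aln[aln$qname %in% oea_q, , drop = FALSE]
  anchors <- sub[sub$uniq == "unique", , drop = FALSE]
  mates <- sub[sub$uniq != "unique", , drop = FALSE]
  mates <- mates[match(anchors$qname, mates$qname), , drop = FALSE]
  if (!is.null(target)) {
    keep <- anchors$pos0 + 1L >= target[1] & anchors$pos0 + 1L <= target[2]
    anchors <- anchors[keep, , drop = FALSE]
    mates <- mates[keep, , drop = FALSE]
  }
  if (nrow(anchors) == 0L) return(empty)
  cls <- classify_repeats(mates$seq, repeat_library,
                          min_identity = min_identity, min_len = min_len,
                          dust_threshold = dust_threshold)
  keep <- !is.na(cls$family)
  if (!any(keep)) return(empty)
  anchors <- anchors[keep, , drop = FALSE]
  cls <- cls[keep, , drop = FALSE]
  data.frame(
    qname = anchors$qname,
    anchor_start0 = anchors$pos0,
    anchor_end0 = anchors$pos0 + nchar(anchors$seq),
    anchor_strand = anchors$strand,
    side = ifelse(anchors$strand == "+", "left", "right"),
    family = cls$family,
    mate_region = cls$region,
    mate_offset = cls$offset,
    mate_strand = cls$strand,
    mate_seq = mates$seq[keep],
    stringsAsFactors = FALSE
  )
}

#' Cluster anchor candidates along the reference
#'
#' Single-linkage clustering per (side, family) with inter-anchor gap at
#' most `max_gap`; clusters supported by fewer than `min_support` distinct
#' pairs are discarded. The anchor-based breakpoint estimate is the maximum
#' anchor end for left clusters and the minimum anchor start for right
#' clusters (anchors cannot extend past the junction).
#'
#' @param candidates data.frame from [collect_oea()].
#' @param max_gap maximum gap (bp) between neighbouring anchors in a
#'   cluster; anchor spread is bounded by the fragment length, so the
#'   fragment mean is a natural default.
#' @param min_support minimum distinct supporting pairs per cluster.
#' @return data.frame of `AnchorCluster`s: `side`, `family`, `start0`,
#'   `end0`, `support`, `breakpoint0`, `orient_plus` (votes), plus a
#'   `qnames` list column.
#' @export
cluster_anchors <- function(candidates, max_gap = 300L, min_support = 5L) {
  empty <- data.frame(
    side = character(), family = character(), start0 = integer(),
    end0 = integer(), support = integer(), breakpoint0 = integer(),
    orient_plus = integer(), stringsAsFactors = FALSE
  )
  empty$qnames <- list()
  if (nrow(candidates) == 0L) return(empty)
  out <- empty
  for (grp in split(candidates,
                    paste(candidates$side, candidates$family))) {
    grp <- grp[order(grp$anchor_start0), , drop = FALSE]
    gap_break <- c(FALSE, grp$anchor_start0[-1] -
                     cummax(grp$anchor_end0)[-nrow(grp)] > max_gap)
    cid <- cumsum(gap_break)
    for (cl in split(grp, cid)) {
      qn <- unique(cl$qname)
      if (length(qn) < min_support) next
      side <- cl$side[1]
      bp <- if (side == "left") max(cl$anchor_end0) else min(cl$anchor_start0)
      plus_votes <- sum((cl$side == "left" & cl$mate_strand == "-") |
                          (cl$side == "right" & cl$mate_strand == "+"))
      row <- data.frame(
        side = side, family = cl$family[1],
        start0 = min(cl$anchor_start0), end0 = max(cl$anchor_end0),
        support = length(qn), breakpoint0 = bp,
        orient_plus = plus_votes, stringsAsFactors = FALSE
      )
      row$qnames <- list(qn)
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

# exact substring occurrences of `pat` in `txt`; returns 0-based starts
substr_starts0 <- function(pat, txt) {
  m <- gregexpr(pat, txt, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Refine breakpoints and TSD length from junction-spanning reads
#'
#' Reads that failed to map end-to-end but split exactly into a reference
#' part and an element-terminus part pin the two junctions at base
#' resolution. With the insertion convention used throughout the package
#' (the duplicated block precedes and follows the element), the left
#' junction coordinate minus the right junction coordinate equals the TSD
#' length, since the two reference/element boundaries overlap by the
#' duplicated bases.
#'
#' @param site list with `left` and/or `right` single cluster rows
#'   (from [cluster_anchors()]).
#' @param unmapped_seqs character vector of read sequences without a unique
#'   end-to-end alignment (junction reads live here).
#' @param region a `GenomeRegion`.
#' @param element_seq full element consensus (already oriented; see
#'   `orientation`).
#' @param orientation element orientation to assume, `"+"`, `"-"`, or
#'   `"auto"` to take the better-supported one.
#' @param min_clip minimum element-matching tail (bp).
#' @param min_ref minimum reference-matching part (bp).
#' @param window bp searched around the anchor breakpoint estimates.
#' @return list with `left_bp0` / `right_bp0` (0-based junction
#'   coordinates, `NA` if no junction read), `tsd_length` (`NA` when
#'   unknown), `n_left` / `n_right` junction-read counts, `orientation`,
#'   and `ambiguous` (TRUE when junction evidence conflicted and a
#'   majority vote was taken).
#' @export
refine_breakpoints <- function(site, unmapped_seqs, region, element_seq,
                               orientation = "auto", min_clip = 5L,
                               min_ref = 8L, window = 200L) {
  if (is.null(site$left) && is.null(site$right)) {
    stop("at least one cluster required")
  }
  est <- c(
    if (!is.null(site$left)) site$left$breakpoint0,
    if (!is.null(site$right)) site$right$breakpoint0
  )
  lo <- max(0L, min(est) - window)
  hi <- min(nchar(region$sequence), max(est) + window)
  W <- substr(region$sequence, lo + 1L, hi)

  orientations <- if (orientation == "auto") c("+", "-") else orientation
  best <- NULL
  for (ori in orientations) {
    elt <- if (ori == "+") element_seq else revcomp(element_seq)
    votes_l <- integer(0)
    votes_r <- integer(0)
    elt_len <- nchar(elt)
    uniq_seqs <- unique(unmapped_seqs)
    all_seqs <- if (length(uniq_seqs)) {
      unique(c(uniq_seqs, revcomp(uniq_seqs)))
    } else {
      character(0)
    }
    for (r in all_seqs) {
      {
        L <- nchar(r)
        if (L < min_ref + min_clip) next
        s_all <- seq.int(min_ref, L - min_clip)
        # left junction: reference prefix (length s) + element 5' terminus
        hit_l <- s_all[substring(r, s_all + 1L, L) ==
                         substring(elt, 1L, L - s_all)]
        for (s in hit_l) {
          for (st in substr_starts0(substr(r, 1L, s), W)) {
            votes_l <- c(votes_l, lo + st + s)
          }
        }
        # right junction: element 3' terminus (length s) + reference suffix
        s_all2 <- seq.int(min_clip, L - min_ref)
        hit_r <- s_all2[substring(r, 1L, s_all2) ==
                          substring(elt, elt_len - s_all2 + 1L, elt_len)]
        for (s in hit_r) {
          for (st in substr_starts0(substr(r, s + 1L, L), W)) {
            votes_r <- c(votes_r, lo + st)
          }
        }
      }
    }
    res <- list(
      left_bp0 = majority_vote(votes_l), right_bp0 = majority_vote(votes_r),
      n_left = length(votes_l), n_right = length(votes_r),
      orientation = ori,
      ambiguous = (length(votes_l) > 0 &&
                     max(tabulate_votes(votes_l)) < length(votes_l)) ||
        (length(votes_r) > 0 &&
           max(tabulate_votes(votes_r)) < length(votes_r))
    )
    if (is.null(best) || res$n_left + res$n_right > best$n_left + best$n_right) {
      best <- res
    }
  }
  best$tsd_length <- if (!is.na(best$left_bp0) && !is.na(best$right_bp0) &&
                         best$left_bp0 - best$right_bp0 >= 0L) {
    best$left_bp0 - best$right_bp0
  } else {
    NA_integer_
  }
  best
}

tabulate_votes <- function(v) {
  if (length(v) == 0L) return(0L)
  as.integer(table(v))
}

majority_vote <- function(v) {
  if (length(v) == 0L) return(NA_integer_)
  tab <- table(v)
  as.integer(names(tab)[which.max(tab)])
}

#' Call insertions from paired anchor clusters
#'
#' Left and right clusters of the same family within `max_pair_dist` are
#' paired into candidate sites. The reported position is the right-side
#' breakpoint -- the first duplicated base -- serialized 1-based.
#' Reference-spanning support counts PROPER pairs whose fragment covers the
#' breakpoint with at least `read_len` anchored on each side. Zygosity uses
#' support thresholds rather than allele ratios (capture bias makes the
#' insertion:reference read ratio uninformative): `hom` when spanning
#' support is at most `hom_max`, `het` when both supports reach
#' `min_support`, otherwise `ambiguous`. A call is `novel` when no
#' same-family annotation lies within `novelty_window` of the site.
#'
#' @param clusters data.frame from [cluster_anchors()].
#' @param classes pair classification table (provides PROPER fragment
#'   intervals).
#' @param region a `GenomeRegion` (provides known repeat annotations).
#' @param repeat_library consensus library (for junction refinement).
#' @param unmapped_seqs read sequences available for junction refinement,
#'   or `NULL` to skip refinement.
#' @param min_support minimum insertion support per cluster.
#' @param hom_max maximum reference-spanning pairs for a homozygous call.
#' @param novelty_window bp window for the novelty check.
#' @param read_len read length (bp).
#' @param frag_mean mean fragment length (bp); bounds cluster pairing and
#'   unrefined confidence intervals.
#' @param single_side allow calls supported on one side only.
#' @return data.frame of `InsertionCall`s: `region`, `position` (1-based),
#'   `ci_lo`, `ci_hi`, `family`, `orientation`, `ins_support`,
#'   `ref_support`, `zygosity`, `tsd` (`NA` when unknown), `novel`.
#' @export
call_insertions <- function(clusters, classes, region, repeat_library,
                            unmapped_seqs = NULL, min_support = 5L,
                            hom_max = 1L, novelty_window = 300L,
                            read_len = 36L, frag_mean = 300L,
                            single_side = FALSE) {
  empty <- data.frame(
    region = character(), position = integer(), ci_lo = integer(),
    ci_hi = integer(), family = character(), orientation = character(),
    ins_support = integer(), ref_support = integer(), zygosity = character(),
    tsd = integer(), novel = logical(), stringsAsFactors = FALSE
  )
  if (nrow(clusters) == 0L) return(empty)
  clusters <- clusters[clusters$support >= min_support, , drop = FALSE]
  if (nrow(clusters) == 0L) return(empty)

  lefts <- clusters[clusters$side == "left", , drop = FALSE]
  rights <- clusters[clusters$side == "right", , drop = FALSE]
  sites <- list()
  used_r <- logical(nrow(rights))
  for (i in seq_len(nrow(lefts))) {
    j <- which(!used_r &
                 abs(rights$breakpoint0 - lefts$breakpoint0[i]) <= frag_mean)
    if (length(j)) {
      j <- j[which.min(abs(rights$breakpoint0[j] - lefts$breakpoint0[i]))]
      used_r[j] <- TRUE
      sites[[length(sites) + 1L]] <- list(left = lefts[i, , drop = FALSE],
                                          right = rights[j, , drop = FALSE])
    } else if (single_side) {
      sites[[length(sites) + 1L]] <- list(left = lefts[i, , drop = FALSE],
                                          right = NULL)
    }
  }
  if (single_side && any(!used_r)) {
    for (j in which(!used_r)) {
      sites[[length(sites) + 1L]] <- list(left = NULL,
                                          right = rights[j, , drop = FALSE])
    }
  }
  if (length(sites) == 0L) return(empty)

  proper <- classes[classes$class == "PROPER", , drop = FALSE]
  out <- empty
  for (site in sites) {
    fams <- unique(c(site$left$family, site$right$family))
    family <- if (length(fams) == 1L) fams else "ambiguous"

    # element orientation by mate-strand vote across both clusters
    votes_plus <- sum(site$left$orient_plus, site$right$orient_plus)
    total <- sum(site$left$support, site$right$support)
    orientation <- if (votes_plus >= total / 2) "+" else "-"

    refine <- NULL
    if (!is.null(unmapped_seqs) && family %in% names(repeat_library)) {
      refine <- refine_breakpoints(
        site, unmapped_seqs, region,
        element_seq = repeat_library[[family]], orientation = orientation
      )
    }
    est_l <- site$left$breakpoint0 %||% NA_integer_
    est_r <- site$right$breakpoint0 %||% NA_integer_
    refined <- !is.null(refine) && !is.na(refine$right_bp0)
    pos0 <- if (refined) refine$right_bp0 else
      if (!is.na(est_r)) est_r else est_l
    tsd <- if (!is.null(refine)) refine$tsd_length else NA_integer_
    if (refined && !is.na(refine$left_bp0)) {
      ci_lo0 <- pos0; ci_hi0 <- pos0
    } else {
      span <- range(c(est_l, est_r, pos0), na.rm = TRUE)
      ci_lo0 <- max(0L, span[1] - read_len)
      ci_hi0 <- min(nchar(region$sequence), span[2] + read_len)
    }

    spanning <- sum(!is.na(proper$frag_start0) &
                      proper$frag_start0 <= pos0 - read_len &
                      proper$frag_end0 >= pos0 + read_len)
    both_sided <- !is.null(site$left) && !is.null(site$right)
    ins_support <- sum(site$left$support, site$right$support)
    zygosity <- if (spanning <= hom_max) "hom" else
      if (spanning >= min_support && ins_support >= min_support &&
          (both_sided || single_side)) "het" else "ambiguous"

    novel <- TRUE
    if (length(region$repeats) && family %in% region$repeats$family) {
      same <- region$repeats[region$repeats$family == family]
      d <- GenomicRanges::distance(
        GenomicRanges::GRanges(region$name,
                               IRanges::IRanges(pos0 + 1L, pos0 + 1L)),
        same
      )
      if (any(!is.na(d) & d <= novelty_window)) novel <- FALSE
    }

    out <- rbind(out, data.frame(
      region = region$name, position = pos0 + 1L,
      ci_lo = ci_lo0 + 1L, ci_hi = ci_hi0 + 1L,
      family = family, orientation = orientation,
      ins_support = ins_support, ref_support = spanning,
      zygosity = zygosity, tsd = tsd, novel = novel,
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Detect insertions end-to-end from a pair table
#'
#' Convenience orchestration: align, classify pairs, collect OEA
#' candidates, cluster anchors, refine breakpoints, and call insertions.
#'
#' @param pairs read-pair table ([simulate_read_pairs()] /
#'   [read_fastq_pairs()]).
#' @param region a `GenomeRegion`.
#' @param repeat_library consensus library.
#' @param max_mismatch aligner mismatch cap.
#' @param frag_bounds proper-pair fragment bounds.
#' @param max_gap,min_support,hom_max,novelty_window,frag_mean,single_side
#'   see [cluster_anchors()] and [call_insertions()].
#' @param target optional anchor interval (1-based closed).
#' @return the insertion call table, with the alignment (`aln`), pair
#'   classes (`classes`), candidates and clusters attached as attributes.
#' @export
detect_insertions <- function(pairs, region, repeat_library,
                              max_mismatch = 2L, frag_bounds = c(180, 420),
                              max_gap = 300L, min_support = 5L,
                              hom_max = 1L, novelty_window = 300L,
                              frag_mean = 300L, single_side = FALSE,
                              target = NULL) {
  aln <- align_pairs(pairs, region, max_mismatch = max_mismatch)
  classes <- classify_pairs(aln, frag_bounds = frag_bounds)
  cands <- collect_oea(aln, classes, repeat_library, target = target)
  clusters <- cluster_anchors(cands, max_gap = max_gap,
                              min_support = min_support)
  read_len <- if (nrow(pairs)) nchar(pairs$seq1[1]) else 36L
  unmapped_seqs <- aln$seq[aln$uniq == "unmapped"]
  calls <- call_insertions(
    clusters, classes, region, repeat_library,
    unmapped_seqs = unmapped_seqs, min_support = min_support,
    hom_max = hom_max, novelty_window = novelty_window,
    read_len = read_len, frag_mean = frag_mean, single_side = single_side
  )
  attr(calls, "aln") <- aln
  attr(calls, "classes") <- classes
  attr(calls, "candidates") <- cands
  attr(calls, "clusters") <- clusters
  calls
}

#' Write insertion calls as TSV and BED
#'
#' @param calls call table from [call_insertions()].
#' @param tsv,bed output paths (`NULL` to skip either).
#' @export
write_insertion_report <- function(calls, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    write.table(calls, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed) && nrow(calls)) {
    gr <- GenomicRanges::GRanges(
      calls$region,
      IRanges::IRanges(start = calls$position, width = 1L),
      strand = calls$orientation
    )
    names(gr) <- sprintf("%s_ins", calls$family)
    gr$score <- calls$ins_support
    rtracklayer::export(gr, bed, format = "BED")
  } else if (!is.null(bed)) {
    writeLines(character(0), bed)
  }
  invisible(calls)
}
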