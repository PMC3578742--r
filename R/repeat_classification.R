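#' Low-complexity filtering and repeat-library classification of mates
#'
#' Unmapped mates of one-end-anchored pairs are first filtered for failed
#' reads (mostly-N) and low-complexity sequence, then compared against a
#' repeat consensus library; a confident match identifies the inserted
#' element family and the position of the mate within the element.
#'
#' @name repeat_classification
NULL

#' DUST-style low-complexity score
#'
#' The standard triplet statistic: within each sliding window, with
#' \eqn{c_t} the count of 3-mer \eqn{t}, the window score is
#' \eqn{\sum_t c_t (c_t - 1) / 2 / (k - 1)} for \eqn{k} triplets per
#' window; the read score is the maximum over windows. Pure tandem repeats
#' score high (a mononucleotide run approaches (k-1)/2), random sequence
#' scores below ~1.
#'
#' @param sequence DNA string (non-empty).
#' @param threshold score above which the read is flagged low-complexity.
#' @param window window size in bp (capped at the read length).
#' @return list with `score`, `flagged` (low-complexity or failed), and
#'   `failed` (all-N or >20% N).
#' @export
low_complexity_score <- function(sequence, threshold = 2.0, window = 64L) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  failed <- mean(chars == "N") > MAX_N_FRACTION
  w <- min(window, length(chars))
  score <- 0
  if (w >= 3L && !failed) {
    tri <- substring(sequence, seq_len(nchar(sequence) - 2L),
                     seq_len(nchar(sequence) - 2L) + 2L)
    nwin <- length(tri) - (w - 2L) + 1L
    for (s in seq_len(max(nwin, 1L))) {
      cnt <- table(tri[s:min(s + w - 3L, length(tri))])
      k <- sum(cnt)
      if (k > 1L) {
        score <- max(score, sum(cnt * (cnt - 1) / 2) / (k - 1))
      }
    }
  }
  list(score = score, flagged = failed || score > threshold, failed = failed)
}

#' Build a repeat consensus library from retroelement models
#'
#' @param ... `TEElement` objects (or a single list of them).
#' @return named character vector of full consensus sequences with an
#'   `ltr_len` attribute recording the LTR length per family (0 for
#'   families without LTR structure).
#' @export
te_library <- function(...) {
  elts <- list(...)
  if (length(elts) == 1L && !is(elts[[1]], "TEElement")) elts <- elts[[1]]
  seqs <- vapply(elts, te_sequence, character(1))
  names(seqs) <- vapply(elts, function(e) e$family, character(1))
  attr(seqs, "ltr_len") <- setNames(
    vapply(elts, function(e) nchar(e$ltr_sequence), integer(1)), names(seqs)
  )
  seqs
}

#' Write a repeat library as multi-FASTA / read one back
#'
#' LTR lengths are carried in the FASTA description (`ltr_len=<n>`).
#' @param library named character vector as produced by [te_library()].
#' @param path FASTA file.
#' @export
write_repeat_library <- function(library, path) {
  ll <- attr(library, "ltr_len") %||% setNames(integer(length(library)),
                                               names(library))
  x <- Biostrings::DNAStringSet(unname(library))
  names(x) <- sprintf("%s ltr_len=%d", names(library), ll[names(library)])
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_repeat_library
#' @export
read_repeat_library <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  fam <- sub("\\s.*$", "", names(x))
  ll <- suppressWarnings(as.integer(sub("^.*ltr_len=(\\d+).*$", "\\1",
                                        names(x))))
  ll[is.na(ll)] <- 0L
  out <- setNames(as.character(x), fam)
  attr(out, "ltr_len") <- setNames(ll, fam)
  out
}

#' Classify a read against a repeat consensus library
#'
#' Finds the best local ungapped match (both strands, all relative offsets
#' including partial overhangs) across the library. A hit is returned only
#' if identity >= `min_identity` over >= `min_len` aligned bases. For
#' LTR-internal-LTR consensuses, a hit lying entirely within either LTR
#' copy is reported as region `"LTR"` with both candidate offsets (the two
#' copies are indistinguishable); hits within the internal sequence are
#' `"internal"`; hits straddling an LTR/internal junction are
#' `"ambiguous"`.
#'
#' @param sequence read sequence (should already have passed
#'   [low_complexity_score()]).
#' @param repeat_library named character vector of consensus sequences,
#'   optionally with an `ltr_len` attribute ([te_library()]).
#' @param min_identity minimum identity over the aligned bases.
#' @param min_len minimum aligned length in bp.
#' @return a `RepeatHit` list (`family`, `region`, `offset` -- the 0-based
#'   consensus coordinate where the matched segment starts -- `offsets`,
#'   `strand`, `identity`, `matched_len`) or `NULL` if nothing qualifies.
#' @export
classify_repeat <- function(sequence, repeat_library, min_identity = 0.90,
                            min_len = 20L) {
  if (length(repeat_library) == 0L) stop("empty repeat library")
  sequence <- toupper(sequence)
  best <- NULL
  for (fam in names(repeat_library)) {
    m <- .best_ungapped_match(sequence, repeat_library[[fam]],
                              as.integer(min_len), min_identity)
    if (length(m) == 0L) next
    if (is.null(best) || m[2] > best$matches) {
      best <- list(family = fam, offset = m[1], matches = m[2],
                   alen = m[3], strand = if (m[4] == 0L) "+" else "-")
    }
  }
  if (is.null(best)) return(NULL)
  identity <- best$matches / best$alen

  cons_len <- nchar(repeat_library[[best$family]])
  ltr_len <- unname((attr(repeat_library, "ltr_len") %||%
                       integer())[best$family])
  if (length(ltr_len) == 0L || is.na(ltr_len)) ltr_len <- 0L
  # matched interval on the consensus, 0-based half-open
  lo <- best$offset
  hi <- best$offset + best$alen
  region <- "internal"
  offsets <- best$offset
  if (ltr_len > 0L) {
    int_start <- ltr_len
    int_end <- cons_len - ltr_len
    in_ltr1 <- hi <= int_start
    in_ltr2 <- lo >= int_end
    in_internal <- lo >= int_start && hi <= int_end
    if (in_ltr1 || in_ltr2) {
      region <- "LTR"
      shift <- int_end  # distance between equivalent positions in the copies
      offsets <- if (in_ltr1) c(best$offset, best$offset + shift) else
        c(best$offset - shift, best$offset)
    } else if (!in_internal) {
      region <- "ambiguous"
    }
  }
  structure(
    list(family = best$family, region = region, offset = best$offset,
         offsets = offsets, strand = best$strand,
         identity = identity, matched_len = best$alen),
    class = "RepeatHit"
  )
}

#' Filter and classify a set of mate sequences
#'
#' Applies the failed/low-complexity filter, then [classify_repeat()] to
#' the survivors.
#'
#' @param seqs character vector of read sequences (named or not).
#' @param repeat_library consensus library.
#' @param min_identity,min_len passed to [classify_repeat()].
#' @param dust_threshold passed to [low_complexity_score()].
#' @return data.frame with one row per input read: `seq_index`, `filtered`
#'   (failed or low-complexity), `family`, `region`, `offset`, `strand`,
#'   `identity`, `matched_len` (`NA` where no hit).
#' @export
classify_repeats <- function(seqs, repeat_library, min_identity = 0.90,
                             min_len = 20L, dust_threshold = 2.0) {
  n <- length(seqs)
  out <- data.frame(
    seq_index = seq_len(n), filtered = FALSE, family = NA_character_,
    region = NA_character_, offset = NA_integer_, strand = NA_character_,
    identity = NA_real_, matched_len = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    lc <- low_complexity_score(seqs[i], threshold = dust_threshold)
    if (lc$flagged) {
      out$filtered[i] <- TRUE
      next
    }
    hit <- classify_repeat(seqs[i], repeat_library, min_identity, min_len)
    if (!is.null(hit)) {
      out$family[i] <- hit$family
      out$region[i] <- hit$region
      out$offset[i] <- hit$offset
      out$strand[i] <- hit$strand
      out$identity[i] <- hit$identity
      out$matched_len[i] <- hit$matched_len
    }
  }
  out
}
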