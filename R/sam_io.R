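#' SAM text import and export
#'
#' Round-trips the package's alignment record tables through SAM v1 text
#' (mandatory columns plus the NM tag) so that external aligner output can
#' substitute for the built-in aligner. Internal 0-based starts serialize
#' to 1-based POS; an unmapped mate inherits RNAME/POS from its mapped mate
#' per the standard; mapped reverse-strand records store the reverse
#' complement of the read, as SAM requires.
#'
#' @name sam_io
NULL

FLAG_PAIRED <- 1L; FLAG_UNMAPPED <- 4L; FLAG_MUNMAPPED <- 8L
FLAG_REVERSE <- 16L; FLAG_MREVERSE <- 32L
FLAG_FIRST <- 64L; FLAG_SECOND <- 128L

#' Write alignment records as SAM
#'
#' Uniqueness is encoded in MAPQ (60 unique, 0 multi-mapping or unmapped).
#'
#' @param aln alignment record table from [align_pairs()] (or [read_sam()]).
#' @param region a `GenomeRegion` (provides the `@SQ` header line).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, region, path) {
  a1 <- aln[aln$mate == 1L, , drop = FALSE]
  a2 <- aln[aln$mate == 2L, , drop = FALSE]
  a1 <- a1[order(a1$qname), , drop = FALSE]
  a2 <- a2[order(a2$qname), , drop = FALSE]
  if (!identical(a1$qname, a2$qname)) stop("unpaired alignment records")

  line_for <- function(me, other, first) {
    n <- nrow(me)
    mapped <- me$uniq != "unmapped"
    omapped <- other$uniq != "unmapped"
    flag <- rep(FLAG_PAIRED + if (first) FLAG_FIRST else FLAG_SECOND, n)
    flag <- flag + ifelse(mapped, 0L, FLAG_UNMAPPED) +
      ifelse(omapped, 0L, FLAG_MUNMAPPED) +
      ifelse(mapped & me$strand == "-", FLAG_REVERSE, 0L) +
      ifelse(omapped & other$strand == "-", FLAG_MREVERSE, 0L)
    rname <- ifelse(mapped, me$rname, ifelse(omapped, other$rname, "*"))
    pos <- ifelse(mapped, me$pos0 + 1L, ifelse(omapped, other$pos0 + 1L, 0L))
    mapq <- ifelse(me$uniq == "unique", 60L, 0L)
    cigar <- ifelse(mapped, paste0(nchar(me$seq), "M"), "*")
    rnext <- ifelse(omapped, "=", ifelse(mapped, "=", "*"))
    rnext[!mapped & !omapped] <- "*"
    pnext <- ifelse(omapped, other$pos0 + 1L, ifelse(mapped, me$pos0 + 1L, 0L))
    seq <- ifelse(mapped & me$strand == "-", revcomp(me$seq), me$seq)
    qual <- ifelse(mapped & me$strand == "-",
                   vapply(me$qual, function(q) {
                     paste(rev(strsplit(q, "")[[1]]), collapse = "")
                   }, character(1), USE.NAMES = FALSE),
                   me$qual)
    fields <- paste(me$qname, flag, rname, pos, mapq, cigar, rnext, pnext,
                    0L, seq, qual, sep = "\t")
    ifelse(mapped, paste0(fields, "\tNM:i:", me$nm), fields)
  }

  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", region$name, nchar(region$sequence))
  )
  body <- as.vector(rbind(line_for(a1, a2, TRUE), line_for(a2, a1, FALSE)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment record table
#'
#' Only the mandatory columns and the NM tag are interpreted; malformed
#' lines are reported with their line numbers.
#'
#' @param path SAM file.
#' @return alignment record table (`qname`, `mate`, `rname`, `pos0`,
#'   `strand`, `nm`, `uniq`, `seq`, `qual`) in file order.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "@")
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 11L)
  if (length(bad)) {
    stop(sprintf("malformed SAM line(s): %s",
                 paste(lineno[bad], collapse = ", ")))
  }
  field <- function(i) vapply(parts, `[[`, character(1), i)
  flag <- suppressWarnings(as.integer(field(2)))
  if (anyNA(flag)) {
    stop(sprintf("malformed SAM line(s): %s",
                 paste(lineno[is.na(flag)], collapse = ", ")))
  }
  mapped <- bitwAnd(flag, FLAG_UNMAPPED) == 0L
  rev <- bitwAnd(flag, FLAG_REVERSE) != 0L
  nm <- rep(NA_integer_, length(parts))
  for (i in seq_along(parts)) {
    tags <- parts[[i]][-(1:11)]
    hit <- grep("^NM:i:", tags, value = TRUE)
    if (length(hit)) nm[i] <- as.integer(sub("^NM:i:", "", hit[1]))
  }
  pos <- as.integer(field(4))
  mapq <- as.integer(field(5))
  seq <- field(10)
  qual <- field(11)
  seq[mapped & rev] <- revcomp(seq[mapped & rev])
  qual[mapped & rev] <- vapply(qual[mapped & rev], function(q) {
    paste(rev(strsplit(q, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  data.frame(
    qname = field(1),
    mate = ifelse(bitwAnd(flag, FLAG_FIRST) != 0L, 1L, 2L),
    rname = ifelse(mapped, field(3), NA_character_),
    pos0 = ifelse(mapped, pos - 1L, NA_integer_),
    strand = ifelse(mapped, ifelse(rev, "-", "+"), NA_character_),
    nm = nm,
    uniq = ifelse(!mapped, "unmapped", ifelse(mapq >= 60L, "unique", "multi")),
    seq = seq, qual = qual,
    stringsAsFactors = FALSE
  )
}
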