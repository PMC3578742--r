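# Shared fixtures (memoized per test file) and independent oracles.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

fixture_region <- function() {
  memo("region", build_reference(10000, 0.49, 3, seed = 1))
}

fixture_element <- function() {
  memo("element", build_etn(847, 6834, seed = 7))
}

fixture_mutant <- function(tsd = 6L, orientation = "+") {
  memo(paste0("mutant_", tsd, orientation), {
    region <- fixture_region()
    pos <- choose_insertion_site(region, tsd_length = tsd)
    insert_element(region, fixture_element(), pos, tsd, orientation)
  })
}

fixture_pairs <- function(genotype, seed = 3L, coverage = 50,
                          error_rate = 0, tsd = 6L) {
  memo(paste("pairs", genotype, seed, coverage, error_rate, tsd, sep = "_"), {
    simulate_read_pairs(
      fixture_region(), genotype,
      mutant = if (genotype == "wt") NULL else fixture_mutant(tsd),
      coverage = coverage, error_rate = error_rate, seed = seed
    )
  })
}

fixture_aln <- function(genotype, seed = 3L, ...) {
  memo(paste("aln", genotype, seed, ..., sep = "_"), {
    align_pairs(fixture_pairs(genotype, seed, ...), fixture_region())
  })
}

# --- independent oracles (no package internals) -------------------------

# reverse complement without Biostrings
rc_chr <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# exhaustive Hamming scan over every offset and strand
oracle_scan <- function(read, ref, max_mm) {
  rl <- nchar(read)
  ref_chars <- strsplit(ref, "")[[1]]
  out <- data.frame(pos0 = integer(), strand = character(),
                    nm = integer(), stringsAsFactors = FALSE)
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else rc_chr(read)
    rc <- strsplit(r, "")[[1]]
    for (p in 0:(nchar(ref) - rl)) {
      win <- ref_chars[(p + 1):(p + rl)]
      mm <- sum(rc != win | rc == "N")
      if (mm <= max_mm) {
        out <- rbind(out, data.frame(pos0 = p, strand = strand, nm = mm,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$nm, out$pos0, out$strand), , drop = FALSE]
}

# hypergeometric two-sided Fisher p by explicit enumeration with lchoose
oracle_fisher <- function(a, b, c2, d) {
  m <- a + b; n <- c2 + d; k <- a + c2
  lo <- max(0L, k - n); hi <- min(k, m)
  lp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  obs <- lp(a)
  all_lp <- vapply(lo:hi, lp, numeric(1))
  sum(exp(all_lp[all_lp <= obs + 1e-7]))
}

random_read <- function(n = 36L) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
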