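#' End-to-end pipeline: simulate, map, detect, call variants, summarize
#'
#' One configuration object drives all stages with a single master seed;
#' outputs land in a run directory under fixed names so repeated runs are
#' byte-comparable.
#'
#' @name cli_pipeline
NULL

#' Pipeline configuration with study defaults
#'
#' Defaults mirror the targeted-capture experiment the simulator emulates:
#' a 10-kb region of ~49% repeat content, an ETn with 847-bp LTRs and a
#' 6,834-bp internal sequence inserted with a 6-bp TSD, 36-bp paired-end
#' reads from 300-bp fragments at 50x, a 40% initial VAF threshold, and a
#' 5-read minimum insertion support.
#'
#' @param ... overrides of any default field.
#' @return a named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    region_length = 10000L, repeat_fraction = 0.49, n_families = 3L,
    ltr_len = 847L, internal_len = 6834L, family = "ETn",
    tsd_length = 6L, insertion_position = NA_integer_, orientation = "+",
    genotype = "het", coverage = 50, read_len = 36L,
    frag_mean = 300, frag_sd = 30, error_rate = 0.005, capture_eps = 0.05,
    max_mismatch = 2L, min_support = 5L, max_gap = 300L, hom_max = 1L,
    novelty_window = 300L, variant_preset = "initial", min_depth = 8L,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

#' Write / read a pipeline configuration as a flat key=value file
#'
#' @param config a `PipelineConfig`.
#' @param path text file path.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) paste(x[-1], collapse = "="))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  defaults <- pipeline_config()
  for (k in names(vals)) {
    v <- vals[[k]]
    proto <- defaults[[k]]
    vals[[k]] <- if (identical(v, "NA")) proto[NA]
      else if (is.integer(proto)) as.integer(v)
      else if (is.numeric(proto)) as.numeric(v)
      else v
  }
  do.call(pipeline_config, vals)
}

#' Choose an insertion site in unique (non-repeat) sequence
#'
#' Picks the repeat-free stretch able to hold `flank` unique bases on each
#' side of the site, preferring the one nearest the region midpoint.
#'
#' @param region a `GenomeRegion`.
#' @param flank required unique flank (bp).
#' @param tsd_length TSD length the site must accommodate.
#' @return 1-based insertion position.
#' @export
choose_insertion_site <- function(region, flank = 400L, tsd_length = 6L) {
  mask <- repeat_mask(region)
  need <- 2L * flank + tsd_length
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0L) stop("no unique stretch long enough for insertion")
  centers <- (starts[ok] + ends[ok]) %/% 2L
  best <- ok[which.min(abs(centers - length(mask) %/% 2L))]
  (starts[best] + ends[best]) %/% 2L
}

#' Run the full pipeline
#'
#' Stages: simulate (reference, element, haplotypes, reads, truth), map
#' (alignment + SAM), detect (insertion report), variants (VAF calls),
#' stats (coverage summary and depth histogram). Any stage failure aborts
#' with the stage name and cause. Outputs use fixed file names inside
#' `out_dir`; the run log records the config hash and master seed.
#'
#' @param config a `PipelineConfig`.
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with `calls`, `variants`, `coverage`,
#'   `region`, `element`, and the output paths.
#' @export
run_end_to_end <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cfg <- config
  write_config(cfg, path("config.txt"))
  cfg_hash <- unname(tools::md5sum(path("config.txt")))
  log <- c(sprintf("config_hash: %s", cfg_hash),
           sprintf("master_seed: %d", cfg$seed))

  sim <- stage("simulate", {
    region <- build_reference(cfg$region_length, cfg$repeat_fraction,
                              cfg$n_families, seed = cfg$seed)
    element <- build_etn(cfg$ltr_len, cfg$internal_len, seed = cfg$seed,
                         family = cfg$family)
    mutant <- NULL
    if (cfg$genotype != "wt") {
      pos <- cfg$insertion_position
      if (is.na(pos)) {
        pos <- choose_insertion_site(region, tsd_length = cfg$tsd_length)
      }
      mutant <- insert_element(region, element, pos, cfg$tsd_length,
                               cfg$orientation)
    }
    pairs <- simulate_read_pairs(
      region, genotype = cfg$genotype, mutant = mutant,
      coverage = cfg$coverage, read_len = cfg$read_len,
      frag_mean = cfg$frag_mean, frag_sd = cfg$frag_sd,
      error_rate = cfg$error_rate, capture_eps = cfg$capture_eps,
      seed = cfg$seed, sample_name = cfg$genotype
    )
    ref_out <- Biostrings::DNAStringSet(setNames(region$sequence,
                                                 region$name))
    Biostrings::writeXStringSet(ref_out, path("reference.fasta"))
    write_repeat_library(te_library(element), path("repeat_library.fasta"))
    write_repeats_bed(region, path("repeats.bed"))
    write_fastq_pairs(pairs, path("reads"))
    truth <- attr(pairs, "truth")
    write.table(
      data.frame(sample = truth$sample, genotype = truth$genotype,
                 position_1based = truth$insertion_position,
                 tsd = truth$tsd_length, family = truth$family,
                 orientation = truth$orientation),
      path("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
    )
    list(region = region, element = element, mutant = mutant, pairs = pairs)
  })
  log <- c(log, sprintf("simulate: %d read pairs", nrow(sim$pairs)))

  frag_bounds <- c(cfg$frag_mean - 4 * cfg$frag_sd,
                   cfg$frag_mean + 4 * cfg$frag_sd)
  mapres <- stage("map", {
    aln <- align_pairs(sim$pairs, sim$region,
                       max_mismatch = cfg$max_mismatch)
    classes <- classify_pairs(aln, frag_bounds = frag_bounds)
    write_sam(aln, sim$region, path("alignments.sam"))
    list(aln = aln, classes = classes)
  })
  log <- c(log, sprintf("map: %d/%d mates uniquely mapped",
                        sum(mapres$aln$uniq == "unique"),
                        nrow(mapres$aln)))

  calls <- stage("detect", {
    library <- te_library(sim$element)
    cands <- collect_oea(mapres$aln, mapres$classes, library)
    clusters <- cluster_anchors(cands, max_gap = cfg$max_gap,
                                min_support = cfg$min_support)
    unmapped_seqs <- mapres$aln$seq[mapres$aln$uniq == "unmapped"]
    calls <- call_insertions(
      clusters, mapres$classes, sim$region, library,
      unmapped_seqs = unmapped_seqs, min_support = cfg$min_support,
      hom_max = cfg$hom_max, novelty_window = cfg$novelty_window,
      read_len = cfg$read_len, frag_mean = cfg$frag_mean
    )
    write_insertion_report(calls, tsv = path("insertions.tsv"),
                           bed = path("insertions.bed"))
    calls
  })
  log <- c(log, sprintf("detect: %d insertion call(s)", nrow(calls)))

  variants <- stage("variants", {
    v <- pileup_and_call(mapres$aln, sim$region,
                         preset = cfg$variant_preset,
                         min_depth = cfg$min_depth)
    write_variant_report(v, path("variants.tsv"))
    v
  })
  log <- c(log, sprintf("variants: %d call(s)", nrow(variants)))

  coverage <- stage("stats", {
    cov <- coverage_stats(mapres$aln, sim$region, classes = mapres$classes)
    write_coverage_report(cov, summary_tsv = path("coverage_summary.tsv"),
                          histogram_tsv = path("depth_histogram.tsv"))
    write_covered_bed(cov, sim$region, path("covered.bed"))
    cov
  })
  log <- c(log, sprintf("stats: mean depth %.1f, %.1f%% covered",
                        coverage$mean_depth,
                        100 * coverage$fraction_covered))

  writeLines(log, path("run_log.txt"))
  invisible(list(
    calls = calls, variants = variants, coverage = coverage,
    region = sim$region, element = sim$element, mutant = sim$mutant,
    aln = mapres$aln, classes = mapres$classes, out_dir = out_dir
  ))
}
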