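Package: etnscan
Title: Detection of Endogenous Retrovirus Insertions from Targeted-Capture Paired-End Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects novel LTR-retrotransposon (ETn family) insertions from short
    paired-end targeted-capture sequencing by mining one-end-anchored read pairs:
    one mate maps uniquely to the target region while the other matches a
    repeat-consensus library. Includes a targeted-capture read simulator with
    known truth (LTR-internal-LTR element model, target-site duplication,
    repeat-aware capture bias), a unique-mapping ungapped short-read aligner with
    SAM import/export, DUST-style low-complexity filtering, anchor clustering with
    junction-read breakpoint and TSD refinement, zygosity and novelty calling,
    a VAF-threshold variant scan with coverage statistics, tandem-repeat copy
    counting, and supporting statistics (Pfaffl expression ratios, Student's t,
    two-sided Fisher exact test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
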