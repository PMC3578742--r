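---
title: "Detecting endogenous-retrovirus insertions from one-end-anchored read pairs"
author: "etnscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting endogenous-retrovirus insertions from one-end-anchored read pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etnscan)
```

## The problem

Short-read resequencing of a candidate interval can fail to reveal a causal
mutation when that mutation is not a point change but the insertion of a
mobile element. An LTR retrotransposon of the mouse ETn family is
kilobases long, highly repetitive, and invisible to a variant scan: reads
from inside the element do not map to the reference, and reads spanning
its junctions map partially or not at all. `etnscan` implements the mining
strategy that recovers such insertions from exactly the reads a standard
pipeline discards. A read pair in which one mate maps uniquely inside the
target region while its mate fails to map -- but matches a repeat
consensus -- is a *one-end-anchored* (OEA) pair, and a pile of OEA anchors
at a consistent position on both sides of a site is the signature of a
non-reference element insertion.

The package covers the full desk-scale workflow: a targeted-capture read
simulator with known truth, a unique-mapping ungapped aligner with SAM
import/export, low-complexity filtering and repeat-library classification
of the unmapped mates, anchor clustering and insertion calling with
junction-read breakpoint refinement, a VAF-threshold variant scan with
coverage statistics, tandem-repeat copy counting, and the supporting
statistics (Pfaffl expression ratios, Student's t, exact Fisher test).

## The element and insertion model

An ETn-class element is modelled as `LTR + internal + LTR` with the two
long terminal repeats *identical by construction*, mirroring real ETn
structure (here 847-bp LTRs flanking a 6,834-bp internal sequence,
8,528 bp in total). Retroviral integration duplicates a few bases of host
sequence on either side of the element (the target-site duplication,
TSD). The package fixes one coordinate convention everywhere:

* the insertion **position** is the 1-based coordinate of the *first
  duplicated base*;
* a TSD of length $t$ at position $p$ produces the mutant haplotype
  `ref[1 .. p+t-1] + element + ref[p .. L]`.

No reference base is ever lost, and the mutant length is exactly
`reference + element + t` -- both properties are enforced by tests over
many `(p, t)` combinations. With this convention the left junction
coordinate minus the right junction coordinate equals $t$, which is how
`refine_breakpoints()` estimates the TSD: the two junctions, each pinned
by split reads, overlap by exactly the duplicated bases.

## What the simulator emulates (and what it does not)

`build_reference()` plants diverged copies (2% substitutions per copy by
default) of a few random family consensus sequences until a requested
fraction of the region is annotated repeat -- the default 0.49 reflects a
repeat-rich mammalian interval where roughly half the sequence is
LINE/SINE-like. Multiple near-identical copies make multi-mapping real
rather than simulated by fiat. `simulate_read_pairs()` then draws
inward-facing FR pairs of 36-bp reads from fragments of length
$\mathrm{Normal}(300, 30)$ truncated to $[2 \times 36, 600]$ --
sonication-sized fragments sequenced on an early short-read instrument.

Capture enrichment is emulated at the fragment level: probes designed on
repeat-masked sequence cannot recover fragments lying inside repeats, so
each proposed fragment is accepted with probability
$\max(\varepsilon, f_u)$ where $f_u$ is its unique-sequence overlap
fraction and $\varepsilon = 0.05$ is a carry-over floor. This reproduces
the key asymmetry of real capture data: insertion-supporting fragments
(which overlap the element) are depleted relative to reference-allele
fragments, so allele-ratio reasoning is unreliable at an insertion site.
Heterozygous samples draw fragments from both haplotypes with equal prior
*before* capture bias, which is what makes the post-capture skew emerge
naturally. Base-call errors are uniform substitutions (default 0.005 per
base) with constant qualities.

Deliberately not modelled: realistic mouse repeat taxonomy, GC bias,
indel errors, chimeric fragments, and open-reading-frame structure of the
element internal sequence. Passing tests therefore demonstrate the
correctness of the inference logic under a faithful *statistical*
emulation of capture sequencing, not performance on any particular real
library.

## Alignment

The aligner is intentionally minimal: ungapped (Hamming) alignment of
short reads against a desk-scale reference, reporting *every* position on
both strands within `max_mismatch` (default 2). Uniqueness requires a
strictly better best mismatch tier; equal-best ties are classed `multi`.
Candidate positions come from exact k-mer seeds. We use
`max_mismatch + 1` non-overlapping seeds per read (12-mers for 36-bp
reads): by pigeonhole, any alignment with at most `max_mismatch`
mismatches contains at least one exact seed, so the seeded search provably
returns the same hit set as an exhaustive scan -- a property the test
suite checks against an independently coded brute-force oracle. (Two
18-bp seeds, the other natural choice for 36-bp reads, cannot make this
guarantee: one mismatch in each half defeats both seeds.) Reads with more
than 20% `N` are returned unmapped; seeds shorter than 8 bp trigger a
naive full scan instead.

Pair classification follows the usual definitions: `PROPER` pairs are
unique/unique, opposite-strand, inward-facing, with an inferred fragment
length inside `frag_mean ± 4·frag_sd`; `OEA` pairs have exactly one
unique end (the mate unmapped *or* multi-mapping -- a mate inside one of
two identical LTR copies is multi, and is exactly the mate we want to
interrogate).

## From OEA pairs to an insertion call

Unmapped mates are first screened with a DUST-style triplet score
(windows of 64 bp; score $\sum_t c_t(c_t-1)/2 / (k-1)$; threshold 2.0) to
drop low-complexity sequence, and mostly-`N` reads are discarded as
failed. Survivors are compared against the repeat consensus library by
best local ungapped overlap over both strands, requiring at least 90%
identity over at least 20 aligned bases; for an LTR-internal-LTR
consensus a hit inside either LTR copy is reported with both candidate
offsets, since the copies are indistinguishable.

Anchors are clustered per side (forward anchors upstream = `left`,
reverse anchors downstream = `right`) and family by single linkage with
gap at most `max_gap` (default 300 bp, the fragment mean -- anchor spread
cannot exceed the fragment length). Clusters below `min_support = 5`
distinct pairs are discarded; the threshold is applied per cluster. A
call normally requires paired left and right clusters within one
fragment-length of each other (`single_side = TRUE` relaxes this).

Breakpoints are refined from junction reads: unmapped reads that split
into a reference part (>= 8 bp, located near the anchor estimates) and an
element-terminus part (>= 5 bp clipped tail). Matching is exact, which is
the right trade-off for 36-bp reads where a junction read carries only a
short clipped tail; at the default 0.005 error rate the large majority of
junction reads are still error-free, and each side's breakpoint is taken
by majority vote (conflicting votes are flagged ambiguous). When both
junctions are pinned, `tsd = left - right` and the confidence interval
collapses to the reported base; without junction reads the interval falls
back to the anchor estimates widened by one read length.

Zygosity uses support thresholds rather than allele ratios -- capture
bias makes the insertion:reference read ratio systematically skewed, so a
binomial/ratio test would be anticonservative. A site with at most
`hom_max = 1` reference-spanning PROPER pairs (fragment covering the
breakpoint with a full read anchored on each side) is `hom`; one where
both insertion support and spanning support reach `min_support` is
`het`; anything else is `ambiguous`. A call is `novel` when no
same-family annotation lies within `novelty_window` (default 300 bp) of
the site. Element orientation comes from a mate-strand vote: for a
plus-orientation insertion, left-side mates read the element in reverse
and right-side mates forward.

## Variant scan, coverage, microsatellites

The VAF caller works on pileups of unique-class alignments only. At each
column the dominant non-reference base defines the variant allele
fraction; `het` is called when `het_min <= VAF < 0.75` and `hom_alt`
above. Two presets mirror a two-pass heterozygous-discovery design: an
`initial` 40% threshold and a `relaxed` 25% threshold, so a 0.30-VAF
column is called only under the relaxed preset, and the 40% call set is
always a subset of the 25% set. Columns below `min_depth = 8` are
skipped -- at the several-hundred-fold depths typical of captured
intervals this floor is immaterial, but it prevents threshold
instability at trivial depths in simulations. Because the aligner is
ungapped the scan is effectively SNV-only; this is a documented
limitation, not an oversight.

`coverage_stats()` reports covered bases (depth >= 1), fraction covered,
mean depth over the interval, the proper-pair fraction, and a binned
depth histogram. `count_tandem_repeats()` returns the leftmost longest
run of exact head-to-tail motif copies -- enough to genotype a
length-polymorphic microsatellite marker (e.g. 15 vs 16 TATC copies
distinguishing alleles).

## Supporting statistics

`pfaffl_ratio()` implements the efficiency-corrected relative expression
ratio $E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$ with
$\Delta Ct = \overline{Ct}_{calibrator} - \overline{Ct}_{sample}$;
efficiencies default to 2 (perfect doubling) when unmeasured, and the
calibrator normalizes to exactly 1. `student_t_test()` is the classic
pooled-variance two-sample t (Welch behind a flag), with the degenerate
zero-variance convention p = 1 for equal means and p = 0 otherwise.
`fisher_exact_two_sided()` sums hypergeometric probabilities of all
tables with the observed margins whose probability does not exceed the
observed table's (probability-mass rule, no mid-p), in log space; the
test suite checks it against full enumeration for every margin with
total at most 30.

## Numerical and design choices

* **Determinism.** Every stochastic step takes one master seed; stream
  seeds are derived by fixed offsets, and equal seeds give byte-identical
  FASTQ and reports.
* **Tie-breaks.** Alignment hits list the best mismatch tier first,
  leftmost first within a tier; repeat hits prefer more matching bases,
  then higher identity, then the leftmost offset; tandem-repeat ties go
  to the leftmost run; junction votes use the majority, flagging
  conflicts.
* **Degenerate inputs.** Zero-length references, empty motifs, all-zero
  contingency tables, and single-replicate t-test groups raise errors;
  `tsd = 0` insertions, empty candidate sets, and alignment tables with
  no mapped reads flow through and produce empty-but-well-formed results.
* **Problem sizes.** The validation suite runs on 10-kb references at
  50x (about 10,000 pairs), with a 20-seed het/hom/wt sweep for
  end-to-end recovery; these sizes give stable behaviour (hundreds of
  supporting reads per simulated site) while keeping a full run to a few
  seconds on one CPU.

## Known limitations

Single-region, single-element detection only: no genome-wide scanning,
no solo-LTR or 5'-truncated insertions, no nested elements. The aligner
is ungapped and quality-blind, appropriate for 36-bp reads but not for
modern read lengths. Junction matching is exact, so breakpoint refinement
degrades (gracefully, to anchor-interval resolution) at high error
rates. The simulator's repeat families are statistical stand-ins, not a
curated mouse repeat taxonomy.
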