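---
title: "Quantifying locus-specific LINE-1 expression from long-read RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locus-specific LINE-1 expression from long-read RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1xpress)
```

## The problem

LINE-1 (L1) is the only autonomous retrotransposon still active in the human
genome: a ~6 kb element whose full-length transcript carries two open reading
frames and replicates by a copy-and-paste mechanism through an RNA
intermediate. Because the genome contains hundreds of thousands of mostly
degenerate L1 copies, short reads arising from an L1 transcript rarely map
uniquely, and locus-level expression estimates from short-read RNA-seq are
unreliable. Long reads (ONT, PacBio) can span most of a full-length L1
transcript and be placed confidently, but the signal is buried in technical
artifacts: degraded or truncated molecules, reads from old high-divergence
copies, reads that merely graze an annotated element, and loci supported by a
single spurious placement.

`l1xpress` implements a stringent detection-and-quantification pipeline for
full-length, young L1 elements. It takes per-sample long reads, a
RepeatMasker annotation of those reads, and splice-aware genome alignments,
and produces per-locus and per-category normalized expression values for the
three L1Base2 reference categories: **active** (FLI-L1, both ORFs intact),
**inactive** (FLnI-L1, full-length non-intact), and **ORF2** (intact only in
ORF2).

## Pipeline model

The pipeline is a fixed sequence of filters followed by a coverage-based
quantification. Each stage is exposed as an ordinary function; the
orchestrator `run_l1_pipeline()` chains them.

1. **Read QC** (`qc_reads()`): reads with mean quality below Q7 are dropped,
   as are reads shorter than 1 kb. The read-level quality is the Phred
   transform of the mean per-base error probability,
   $-10\log_{10}\!\big(\tfrac1n\sum_i 10^{-q_i/10}\big)$, the convention
   long-read basecallers use; an arithmetic mean of Q scores would overweight
   good bases. Reads under 1 kb cannot meaningfully support a 4–6 kb element
   and mostly add mapping noise.
2. **Candidate selection** (`select_reads_by_divergence()`): from the
   RepeatMasker `.out` annotation of the reads, a read is kept when *any* of
   its hits is of class `LINE/L1` (prefix match) with divergence strictly
   below 10%. Divergence from the subfamily consensus is a proxy for element
   age; the strict `< 10` boundary restricts the analysis to young,
   potentially mobile copies. The threshold is deliberately conservative
   relative to ONT basecalling error (~3% on R9 data), which inflates
   apparent divergence.
3. **Reference pruning** (`prune_l1_references()`): active regions that
   overlap any inactive region are removed whole (a read in such a region
   cannot be attributed to the active copy), and all three categories then
   lose regions overlapping annotated exons, so that ordinary mRNA coverage
   cannot masquerade as L1 expression. Overlap is strand-blind and a single
   shared base removes the region; regions are never clipped, because a
   clipped element would no longer be the annotated full-length unit.
4. **Containment filter** (`filter_by_containment()`): an alignment is kept
   when at least 90% of its reference span lies within the union of the
   pruned regions. The denominator is the full span including introns (`N`)
   and deletions (`D`); computing against the union means a read bridging
   two adjacent annotation records is not penalized. Each kept read is
   assigned to the single region with the largest span overlap (ties to the
   leftmost region).
5. **Locus filters** (`apply_locus_filters()`), judged per locus and in
   order: fewer than 2 mapped reads (`too_few_reads`); any read start more
   than 100 bp from the most common start (`inconsistent_starts`); modal
   start more than 1.5 kb from the element's reference start
   (`start_too_far`). Autonomous L1 transcription initiates at the 5'
   promoter, so genuine signal shows tightly clustered 5'-proximal starts,
   while library artifacts and internal priming scatter. All thresholds are
   inclusive on the keep side: a deviation of exactly 100 bp, or an offset
   of exactly 1500 bp, is kept.
6. **Quantification** (`quantify_loci()`): split-aware coverage in the
   bedGraph model (depth counts aligned segments; `N` and `D` operations
   contribute nothing; zero-depth intervals are kept so every declared
   sequence is tiled), per-locus mean coverage, normalization by the sample
   read total scaled to millions, and the per-category length-weighted
   average
   $$\mathrm{WeightedAverage}_i \;=\;
     \frac{\sum_{r \in \mathrm{Regions}_i} v_r \cdot L_r}
          {\sum_{r \in \mathrm{Regions}_i} L_r},$$
   where $v_r$ is the normalized per-locus value, $L_r$ the reference
   element length, and $i$ ranges over the categories. All reference loci of
   a category enter the sum: loci removed by the artifact filters contribute
   $v_r = 0$ but keep their length in the denominator, so the category value
   reflects expression over the whole annotated complement rather than over
   whichever subset survived.

Finally `subfamily_report()` counts expressed active loci for the young
subfamilies L1HS and L1PA2 (anything else, including unannotated loci, is
pooled as `other`), with subfamilies assigned from the RepeatMasker genome
track row (longer than 4.5 kb) with the largest overlap.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_q` | 7 | Phred | minimum mean read quality |
| `min_len` | 1000 | bases | minimum read length |
| `max_div` | 10 | percent | divergence ceiling, exclusive |
| `min_frac` | 0.9 | fraction | span containment floor, inclusive |
| `min_reads` | 2 | count | minimum reads per locus |
| `start_window` | 100 | bases | tolerated deviation from the modal start |
| `max_start_offset` | 1500 | bases | tolerated modal-start distance from the element start |
| `scale` | 1e6 | — | normalization scale ("per million reads") |

The defaults reproduce the published filter settings and are the values the
whole test suite pins down at their boundaries. Two semantics are
configurable because the underlying convention is genuinely ambiguous:

* **Mean mode.** `mean_coverage()` defaults to `interval_mean`: the
  unweighted mean of the depth values of the bedGraph intervals overlapping
  a region. This replicates mapping a bedGraph onto regions with a mean
  aggregator, which averages interval *values*, not bases, so a narrow
  high-depth interval counts as much as a wide zero interval. The per-base
  alternative (`base_mean`) is offered because the two differ whenever
  overlapping intervals have unequal widths; the package treats
  `interval_mean` as canonical since it is what the reference tooling
  computes.
* **Normalization total.** "Total number of reads in the sample" is taken as
  the count of reads passing the quality filter — the earliest per-sample
  total the pipeline sees — and can be overridden with `total_reads` to
  match other per-dataset conventions (raw count, post-length-filter
  count). The convention used is recorded in the run log.

## Open design choices

Where the underlying procedure is underdetermined, the package fixes a
deterministic rule and exposes the alternative:

* The reference start position for the 1.5 kb rule is the lower genomic
  coordinate (BED start) regardless of strand, matching coordinate-based
  tooling; `strand_aware = TRUE` switches to the biological 5' end (BED end
  for minus-strand elements).
* The 100 bp consistency rule removes the entire locus when any read
  deviates; `trim_outliers = TRUE` instead drops the deviating reads and
  re-judges the remainder.
* Modal-start ties break toward the smaller coordinate; locus-assignment
  ties toward the leftmost region; subfamily ties toward the
  lexicographically smallest name. None of these affect defaults-path
  results on realistic data, but they make every output reproducible.
* Exon exclusion applies to all three categories, and inactive-overlap
  subtraction only to the active set; the ORF2 set is not subtracted against
  the other categories. Active elements are the category used for subfamily
  and locus-level claims, hence the stricter pruning.
* Boundary readings: "less than 10% diverged" is strict; "at least 90%
  contained" is inclusive; "greater than 4.5 kb" for library/track rows is
  strict; "more than 100 bp / 1.5 kb" trigger removal strictly beyond the
  threshold.

## Numerical and degenerate-input behavior

Coverage depths are integers and interval means are exact ratios of small
integers, so oracle comparisons against external tools are bit-exact for
depths and within 1e-9 for means (the external tool prints 10 significant
digits). Zero-read inputs yield a single zero-depth interval per declared
sequence; an empty locus list is an error for the weighted average (there is
no meaningful denominator); `normalize_expression()` refuses a zero read
total; `modal_start()` refuses empty input. BED parsing rejects
`start >= end` with the offending line number rather than silently
reordering.

## What the simulator emulates — and what it does not

`simulate_l1_bundle()` generates a complete synthetic dataset: a two-sequence
toy genome (2 × 100 kb), 15 reference loci across the three categories, 34
reads planted at locus 5' ends with bounded uniform jitter, the matching
RepeatMasker `.out`, a UCSC-style repeat track, exon annotation, and SAM
alignments written directly from the planted geometry (no aligner involved).
Every filter has at least one decoy constructed to fail exactly that filter
and one near-boundary case that passes it (9.9 vs 10.0% divergence, 0.90 vs
0.89 containment, 2 vs 1 reads, 100 vs 101 bp deviation, 1500 vs 1501 bp
offset, 1000 vs 999 bp length), plus a secondary alignment record, a spliced
read, and loci removed at reference pruning. The bundle carries a truth
table; `verify_truth()` asserts that the pipeline reproduces it exactly, and
the test suite does so across 20 seeds.

The simulator intentionally does not model basecalling error, realistic
quality-score distributions, splice-graph structure, polymorphic
(non-reference) L1 insertions, or multi-mapping ambiguity — reads are planted
at their true loci and alignments are exact. Passing the truth-recovery suite
therefore demonstrates that the *filter logic and arithmetic* are correct
under the stated conventions, not that the thresholds are optimal for any
particular platform's error profile. Conclusions about real tissues still
require the caveats that apply to the underlying protocol: library
construction biases against 6 kb transcripts, and divergence thresholds
interact with platform error rates.

## Problem sizes used in validation

The packaged validation runs at deliberately small scale: a 30-region toy
reference replica with hand-computed pruning survivors (10→7 active, 14→12
inactive, 6→5 ORF2), 100 randomized alignment fixtures (≤50 reads, ≤3
sequences each) compared against external-tool oracles, and 20 simulator
seeds of 34 reads each for end-to-end truth recovery. These sizes make the
full suite run in about a minute while still exercising every code path and
boundary; the pipeline itself streams over alignments and scales to
real-sample inputs limited only by memory for the coverage track.

## Limitations

* Quantification is per-sample; cross-sample differential testing is out of
  scope and should be done downstream on the per-locus tables.
* The containment filter uses span semantics (introns count toward the
  denominator) to mirror the reference tooling's default; heavily spliced
  read-through transcripts are therefore penalized, which is the intended
  conservative behavior, but `use_blocks = TRUE` is available.
* A read is assigned to exactly one locus; expression from tandem or nested
  young copies closer than a read length cannot be fully disentangled.
* The subfamily report depends on the completeness of the supplied repeat
  track; loci without a >4.5 kb track overlap are reported as `other`.
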