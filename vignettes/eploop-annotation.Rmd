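---
title: "Annotating enhancer-promoter loops from chromatin marks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating enhancer-promoter loops from chromatin marks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eploopr)
```

## The analysis

`eploopr` turns three peak tracks and a loop list into classified regulatory
elements and enhancer-promoter (EP) loop calls. The operational definitions
are deliberately simple and fully determined by interval overlap:

1. **Significance filter.** A peak participates only if its −log10(P) is
   *strictly* greater than 5 (P < 10⁻⁵). The value is read from narrowPeak
   column 8, the MACS2 convention; because "log P" conventions differ between
   peak callers, the column index is a documented argument of
   `read_narrowpeak()` rather than a hidden assumption.
2. **Element classification.** A promoter is an accessible site carrying all
   three signals (ATAC-seq, H3K4me3, H3K27ac); an enhancer carries ATAC-seq
   and H3K27ac but no H3K4me3. An ATAC site overlapping H3K4me3 alone, or
   nothing, yields no element.
3. **Loop annotation.** Each loop anchor collects the classes of every
   element it overlaps; the loop gets exactly one category by the precedence
   EP > PP > EE > PN/EN > NN. EP requires the promoter and the enhancer on
   *different* anchors.

All coordinates are 0-based half-open throughout (the native convention of
narrowPeak, BED and BEDPE), and "overlap" always means at least one shared
base: touching intervals (`end == start`) do not overlap. The filter is
applied to all three tracks; per-track thresholds can be passed if a user
wants to relax one mark.

### Element representation: two readings of "overlapping signals"

"Regions exhibiting three overlapping signals" admits two readings, and the
package implements both:

- **atac-anchored** (default): each ATAC peak is tested pairwise against the
  two mark tracks and, if classified, the *ATAC interval itself* becomes the
  element. The accessible site is the biologically meaningful anchor unit
  (it is where an sgRNA can actually bind), each ATAC peak yields at most one
  element, and promoter/enhancer sets are disjoint by construction.
- **intersection**: the element is the maximal region simultaneously covered
  by all required tracks — the stricter, mutual-overlap reading. Intervals
  are typically narrower and need not align with any single peak.

Both modes give identical *loop* categories whenever anchors are much wider
than peaks (the common case at 5-25 kb loop resolution); they differ mainly
in the element intervals reported.

### Loop handling

Loop lists are consumed, not produced: generic BEDPE and the Juicer hiccups
header dialect are both read, anchors are canonically ordered, and loops
listed at several resolutions are collapsed only on *exact* anchor equality,
keeping a multiplicity count — near-duplicates at different resolutions are
left alone because merging them is the loop caller's job. Whether to pool
per-resolution lists or use the caller's merged list is the user's choice;
the package accepts either (multiple paths are pooled before dedup).
Chromosome names are normalized only through an explicit alias map
(`c("1" = "chr1")`), never guessed.

Three deliberate edge-case policies: an anchor overlapping both a promoter
and an enhancer does not veto an EP call (the partner anchor decides) but
flags the loop `ambiguous`; inter-chromosomal loops are annotated normally
but carry no distance; anchors may be padded symmetrically via `padding`,
default 0 bp, since the motivating workflow used none. Distance is
midpoint-to-midpoint of the anchors, the natural convention at anchor
resolution.

## Bridge-linker read splitting

Bridge-linker Hi-C ligates a short adapter between proximity-ligated
fragments; a read spanning the junction must be cut before alignment. The
search is a fixed-width Hamming scan (`Biostrings::matchPattern`), optionally
on both strands: linkers are short and their errors substitution-dominated,
so indels are not modelled; the default tolerance is 1 mismatch. The linker
sequence is protocol-specific and therefore a mandatory parameter with no
default.

Policies, chosen once and documented rather than inherited from any
particular implementation: with one hit, both flanks are emitted with
qualities sliced in lockstep; with two or more hits only the *outermost*
flanks survive (internal fragments between two linkers are ligation
artifacts) and the read is flagged `multi_linker`; linker-free reads pass
through to their own stream. No fragment shorter than `min_fragment_len`
(default 20 bp, the usual alignment-length floor) is ever written, and
per-read statuses always sum to the input count. In paired-end mode each
mate is trimmed independently at its first linker, keeping the 5′ genomic
flank — the sequence past the junction belongs to the ligation partner.

## sgRNA selection

From a CHOPCHOP-like candidate table the rule is: (i) perfect on-target
match (`on_target_mismatches == 0`); (ii) efficiency strictly greater
than 60 (a score of exactly 60 fails); (iii) rank survivors ascending
lexicographically on the off-target counts (MM0, MM1, MM2, MM3) — a site
with fewer perfect off-targets always beats one with fewer 2- or 3-mismatch
off-targets, the natural severity ordering. Ties are broken by higher
efficiency and then input order; the tie-break is this package's decision,
made explicit so rankings are reproducible. The CRISPRi targeting window is
−50 bp to +400 bp around the TSS, both ends inclusive, and
`annotate_chromatin()` reports which peak tracks support each guide site.

## Quantification formulas

- **2^−ΔΔCt**: per sample ΔCt = target − reference; ΔΔCt subtracts the
  *arithmetic mean* calibrator ΔCt (the standard Livak convention); fold
  = 2^−ΔΔCt. Consequently the calibrator's geometric-mean fold is exactly 1
  and `log2(fold) == −ΔΔCt` to machine precision — both are tested
  identities, useful as self-checks on real tables. Ct values are required
  to lie in (0, 45) cycles.
- **Pairwise Bonferroni**: P = 2α / (k(k−1)) = α / C(k, 2) for k groups at
  family-wise level α (default 0.05); at k = 2 it reduces to α. Only this
  bespoke threshold is implemented — ANOVA and chi-square tests themselves
  are ordinary `stats` calls.
- **Survival rate**: survivors / total, guarded against zero totals.
- **Stain quantification**: a pixel is stain-positive iff every RGB channel
  lies within its inclusive [min, max] bounds. Published settings often give
  a single value per channel (e.g. B = 105, G = 150, R = 190) without saying
  which side of the threshold is kept; the package therefore requires
  explicit bounds per channel rather than guessing a direction. The
  hemoglobin index is positive pixels / yolk pixels; by default the positive
  mask is first restricted to the yolk (both areas come from the same embryo
  image), with `restrict_to_yolk = FALSE` available.

## The synthetic-data generator

Every pipeline input can be generated from a seed with planted truth:
peak tracks whose −log10(P) values straddle the filter threshold (including
one decoy at exactly 5.0 to pin the strict inequality), loops of every
category, chimeric reads with recorded junctions, Ct tables with planted
folds, and a two-mask stain image with an exact planted area fraction.

Design points:

- **Determinism.** Each stage draws from a sub-seed derived from the master
  seed, so identical (seed, config) pairs give byte-identical files and
  adding a stage never perturbs another.
- **Geometry.** Elements occupy non-overlapping slots four anchor-widths
  wide and sit at slot centers, so a loop anchor (default 5 kb) centered on
  one element can never graze a neighbor; element classes are round-robined
  across chromosomes so every loop category can be placed
  intra-chromosomally. Anchor and mark boundaries can be jittered
  (`boundary_jitter_bp`); below the slot margin this provably cannot change
  any overlap decision, which is what the jitter-robustness test exercises.
- **Decoys** cover each failure mode of the classifier: sub-threshold
  triple-mark sites, ATAC-only, H3K4me3-only, H3K27ac-only and ATAC+H3K4me3
  sites, plus loops with one or no annotated anchor.
- **Scale.** Defaults are a toy study — 2 chromosomes × 1 Mb, 10 promoters,
  10 enhancers, 20 decoys, 35 loops, 500 chimeric reads with 30-60 bp
  flanks, knockdowns of 20/50/80 % with 9 samples per group and 0.1-cycle
  Ct noise, a 100 × 100 px image with a quarter of the yolk stained — sizes
  at which the whole suite, including 100 replicate Ct tables, runs in well
  under a minute while still containing every planted structure.

What the generator does *not* emulate: realistic peak-width and signal
distributions, overlapping or nested regulatory elements, copy-number and
mappability artifacts, sequencing errors inside reads, qPCR efficiency
differences between amplicons, or staining gradients in images. Perfect
recovery on synthetic data therefore demonstrates correctness of the
*decision rules*, not robustness to the noise structure of real data — on
real tracks the filter threshold and the atac-anchored/intersection choice
will matter far more than they do here.

## Numerical and degenerate-input choices

- Interval joins run through `GenomicRanges::findOverlaps` after an explicit
  0-based → 1-based shift; the elementary overlap predicate is also exposed
  (`interval_overlaps()`) and is property-tested against a per-base
  enumeration oracle.
- The peak filter, the efficiency filter and the TSS window are boundary
  cases by construction, so each is pinned by tests at its exact edge
  (5.0 vs 5.0 + ε; 60.0 vs 60.1; −50/−51 and 400/401).
- Degenerate loops (self-overlapping anchors) and inter-chromosomal loops
  are flagged, never dropped; parsing never silently discards a data line —
  malformed input aborts with the line number.
- Empty inputs (no peaks, no loops, no reads) produce empty, fully-typed
  outputs rather than errors.

## Known limitations

- Elements are unstranded and promoters are defined purely epigenomically;
  no TSS annotation is consulted, so a bidirectional promoter is one
  element.
- EP assignment is purely positional: a loop connecting an enhancer to a
  promoter does not establish which *gene* is regulated.
- The linker search does not model indels; a linker containing an insertion
  will be missed at any mismatch budget.
- `summarize_by_chromosome()` attributes inter-chromosomal loops to the
  first (canonically ordered) anchor's chromosome.
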