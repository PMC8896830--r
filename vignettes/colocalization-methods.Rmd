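---
title: "Methods: co-localization of 5hmC and R-loops at active genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-localization of 5hmC and R-loops at active genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicoloc)
```

## The question and the model

TET enzymes oxidize 5-methylcytosine to 5-hydroxymethylcytosine (5hmC);
R-loops are three-stranded structures of a DNA:RNA hybrid plus displaced
single-stranded DNA that form co-transcriptionally. Both accumulate in
gene bodies of transcribed genes, and the analytical question this
package answers is whether they accumulate at the *same* genes and the
*same* positions more often than chance placement within transcribed
chromatin would produce — and what consequences co-occupancy has for
transcription termination (readthrough past the TTS) and for gene
expression.

The package treats the problem as interval statistics over a gene-model
scaffold. All coordinates are 0-based half-open (BED convention); GTF
input is converted on parse. One model per gene is the union span of its
transcripts; the TSS and TTS are the biological 5' and 3' ends, so for a
minus-strand gene the TSS is its `end` coordinate. Transcripts of one
gene on different chromosomes or strands abort with an error rather than
being dropped silently, because silent loss corrupts every downstream
denominator (most visibly the active-gene count).

## Active genes

The active-gene filter keeps genes with TPM strictly greater than a
percentile (default 25) of the per-gene TPM distribution. Two choices
here were genuinely open:

* **Which genes enter the percentile?** All annotated genes, with genes
  absent from the expression table counted as TPM 0. The alternative —
  only detected genes — shifts the threshold upward and makes the
  denominator depend on the detection pipeline; the full-set-with-zeros
  rule is the default and `missing_as_zero = FALSE` gives the other
  behavior.
* **Which percentile estimator?** Linear interpolation (type-7
  quantile), the common default; the threshold used is recorded on the
  result as an attribute.

## Coverage, profiles, metagenes

Reads are extended in the 3' direction to 150 nt (5' end fixed, clipped
at chromosome bounds) and binned with *fractional* assignment: a read
contributes `overlap/length` to each bin it touches, so each read adds
exactly 1 across the genome — this conservation is asserted in the test
suite. RPKM is `count * 1e9 / (bin_size * total_mapped)`. A 5'-end
counting mode is deliberately absent: fractional assignment is what the
density semantics of RPKM profiles imply.

Profile extraction integrates the binned step function exactly between
arbitrary (possibly fractional) breakpoints, so gene bodies whose length
is not divisible by the bin count are handled without rounding; body-bin
means times bin widths reproduce the per-base body signal to within
1e-9 relative error (tested against a per-base oracle). Conventions the
underlying data do not fix:

* Summit-anchored windows with an even bin count place the summit at the
  left edge of the center-right bin.
* Windows truncated by chromosome ends are dropped (not zero-padded,
  which would bias the mean toward zero) and counted.
* Minus-strand rows are reversed so all profiles run TSS to TTS;
  reversing a strand twice reproduces the original row exactly.
* SEM uses the n−1 denominator across regions; a single region reports
  SEM 0.
* A minimum gene-body length (default 120 bp) gates metagene
  eligibility: 60 body bins are not meaningful below ~2 bp per bin.
* Heatmap rows are ordered by descending mean signal by default
  (`sort_rows = FALSE` preserves input order).

## The permutation overlap test

The test statistic is the **number of query regions overlapping the
subject set by at least 1 bp** — an element-count statistic, matching
the idea of counting "overlapping regions"; the shared base pairs are
computed alongside and reported. The null hypothesis is that, given the
region counts and lengths and the constraint that regions live in
transcribed gene bodies, positions are otherwise random. Each of `N`
iterations re-places **both** sets (single-set mode available)
uniformly within the merged active-gene segments:

* a segment is chosen with probability proportional to its number of
  valid start positions for the length being placed, then the start is
  uniform among valid starts — exactly uniform over all feasible
  placements;
* placements are not forced to be mutually disjoint (any collision rule
  would distort uniformity, and none is implied by the model);
* chromosome identity is not preserved by default (the universe
  constraint is "within transcribed genes", not "on the same
  chromosome"); `within_chrom = TRUE` preserves it;
* the universe excludes the 4 kb assignment flanks by default — the
  flanks exist to catch promoter/terminator peaks during assignment,
  not to claim they are transcribed sequence; callers can pass flanked
  windows as the universe instead;
* an interval longer than every segment is an error naming the length.

The empirical p-value uses the add-one rule `(1 + k)/(1 + N)` where `k`
counts null draws at least as large as the observed statistic. The raw
frequency `k/N` is reported too; the add-one form never returns 0 and
is exactly valid (under the null, `P(p <= a) <= a`). "As extreme as
observed" is read one-sided toward enrichment, since the hypothesis is
overlap enrichment; `alternative = "two.sided"` doubles the smaller
tail. A single master seed derives all iteration streams, and a fixed
seed makes the whole test bit-reproducible.

## Per-gene classification and correlation

A gene is dual-marked when it has at least one assigned peak of each
mark **and** at least one 5hmC peak and one R-loop region overlap each
other within the gene window. The weaker co-assignment-only rule
(`require_mutual_overlap = FALSE`) is available; mutual overlap is the
default because co-assignment of a promoter peak and a terminator
region says little about physical co-localization. The Pearson
correlation concatenates the 60-bin body vectors of both tracks over
active genes; bins where both signals are zero are retained by default
(dropping them conditions on the signal), and a constant input vector
raises an error rather than returning NaN.

## Readthrough

The readthrough index of a gene is the downstream-window RPKM over the
body RPKM. The external tool the field uses for this defines none of
its knobs publicly in a form portable here, so the statistic is
self-contained with documented defaults: a 5000 bp downstream window
truncated at the nearest downstream annotated gene boundary (strand
aware), a 500 bp minimum usable window, and a body floor of 1 RPKM
below which a gene is excluded (an index over a near-zero denominator
is noise).

Two conditions are compared per gene. The enriched set is genes with
`index_B > 1.5 * index_A` and `index_B >= 0.05`; the absolute floor
exists because a gene with `index_A = 0` would otherwise be flagged by
a single stray downstream read. The global comparison: because indices
are matched per gene, the p-value comes from the two-sided Wilcoxon
rank test on the paired differences. The classical unpaired
Mann–Whitney U over the two index distributions is computed and
reported as well (`mw_u`, `p_ranksum`) — with a planted minority of
affected genes the unpaired rank-sum plateaus (its z is bounded by the
planted fraction regardless of effect size or depth), which is why the
paired form is the package's inference of record.

## Enrichment

One-sided Fisher's exact p-values are hypergeometric upper tails;
pathway genes outside the expressed-gene background are dropped (with a
count) before testing, q-values are Benjamini–Hochberg over the tested
pathways, and the default significance flag is q < 0.05. The full table
is always returned — filtering is a flag, not a row drop.

## The synthetic generator

The generator emulates the statistical structure of mark and
readthrough data without any downloads, and its defaults are the study
conditions of the test suite: 400 genes on 2 × 5 Mb chromosomes,
log-normal gene lengths (median 5 kb), log-normal TPMs
(meanlog 2, sdlog 1.2), gamma-distributed region lengths — 5hmC short
and peak-like (median 300 bp), R-loops broader (median 800 bp) —
co-occurrence rate 0.5, TTS bias 2, 2 × 10⁵ reads of 36 bp per library
with a 5% uniform background and 25% peak-enrichment component.

Design points worth knowing:

* Mark-bearing genes are drawn with probability proportional to gene
  length. With TTS bias 0 and co-occurrence 0 this makes independent
  placement exactly uniform over gene-body base pairs, which is the
  null the permutation test shuffles against — so the calibration and
  null-power properties are tested under the null they claim.
* TTS bias is a Beta(1 + bias, 1) relative position along the
  transcription direction; bias 0 is uniform.
* Planted readthrough: downstream read offsets follow a truncated
  exponential (mean = decay length, truncated at the 5 kb readthrough
  window), with the planted read count calibrated so the
  downstream/body density ratio over that window matches the design
  ratio in expectation. Planting is restricted to genes above the
  active percentile — readthrough presupposes transcription.
* Everything is a pure function of (design, seed); fixtures regenerate
  byte-identically and the manifest records the design and per-file
  checksums.

What the generator does **not** model — mappability, GC bias,
duplication, fragment-length variation, peak-caller artifacts — bounds
what passing tests show about real data: they validate the statistics
and their calibration under the stated generative model, not robustness
to library-preparation pathologies.

## Problem sizes and numerical choices

The test suite validates each binned operation against per-base
brute-force oracles on 100 randomized small instances (integer paths
exact, density paths to 1e-9 relative error); the shuffle contract over
10⁴ shuffles; permutation calibration over 200 null datasets at
N = 199 shuffles; power over 50 replicates at N = 999 with
co-occurrence 0.5 and 0; readthrough recovery over 25 replicates of a
500-gene, 50-planted design; and exact-test enumeration over every
2×2 table with N ≤ 60. These sizes keep the full suite in the
few-minute range on one CPU while leaving the binomial 3σ bounds tight
enough to detect miscalibration.

Tie-breaks and degenerate inputs are fixed deterministically
throughout: summit ties break leftmost; an empty peak set classifies
every gene "neither"; empty interval sets yield zero overlap, not an
error; a constant signal vector is an error for the correlation; a
zero-length shuffle universe is an error.

## Known limitations

* Gene models are span-level only — no isoforms, exons or UTRs; signal
  inside introns counts as body signal.
* The shuffle preserves counts and lengths but not GC content, gaps or
  inter-region spacing; against nulls where those matter the test is
  liberal.
* The readthrough index ignores reads from overlapping downstream
  genes beyond the truncation rule; convergent gene pairs closer than
  the minimum window are simply excluded.
* bedGraph is the only track output (no bigWig), and the DE fit itself
  is consumed, never computed — the synthetic DE table is a stub for
  exercising the enrichment stage.
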