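---
title: "Detecting tandem duplications from depth, mapping quality and split reads"
author: "TandemScan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tandem duplications from depth, mapping quality and split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A tandem duplication (TD) is a genomic segment that has been copied one
or more times and inserted immediately adjacent to its source. TDs are a
common class of structural variation with direct relevance to tumor
evolution, and calling them from short-read sequencing is harder than it
sounds: read coverage is uneven, the amplitude of the depth gain depends
on the (unknown) copy count and tumor purity, and the duplicated
sequence confuses the aligner, which shows up as degraded mapping
quality rather than as a clean coverage step.

TandemScan detects TDs in two stages:

1. **Rough detection.** The chromosome is tiled into non-overlapping
   bins; each bin contributes a 2D feature point — read depth (RD) and
   mapping quality (MQ). After GC correction, total-variation denoising
   and scale normalization, bins inside TDs are *outliers* in this
   feature plane: their depth is raised by an unknown amount and their
   MQ is depressed. Rather than thresholding either signal, the caller
   runs DBSCAN over the point cloud and takes the **noise points** — the
   points no dense cluster will claim — as TD candidate bins.
   Consecutive candidate bins merge into rough regions.
2. **Breakpoint refinement.** Reads that span a copy junction align with
   a clip + match CIGAR. A clip-first record (`xS(L-x)M`, here called
   *post-alignment*) starts matching exactly at the low TD boundary, so
   `a = pos`; a clip-last record (`yM(L-y)S`, *pre-alignment*) stops
   matching exactly at the high boundary, so `b = pos + y - 1`. Votes
   from these records move the rough bin-resolution boundaries to
   single-nucleotide resolution.

# Signal model

## Per-position signals

For each reference position the pileup counts every aligned (CIGAR
M/`=`/X) base of every retained record — primary, mapped, non-duplicate;
no MAPQ filter, because depressed MAPQ *is* one of the two features —
and accumulates the records' MAPQ. A read crossing a bin boundary
therefore contributes to both bins. Positions that are N in the
reference are stored as `NA`: dropping them would shift coordinates, and
treating them as zero-coverage would fake a deletion signal. The
per-position MQ is the **mean** MAPQ of the covering reads (the natural
reduction when several reads cover one base; 0 where uncovered).

## Binning and filtering

With bin width `lenBin` (default 2000 bp) the bin's RD is the mean
per-position read count and its MQ the mean per-position MQ. A bin
containing *any* N position has undefined depth and is marked invalid;
invalid bins are excluded from every downstream statistic. A terminal
partial bin is kept when it covers at least half of `lenBin`, otherwise
dropped — a shorter stub estimates depth from too few positions to be
comparable. The GC fraction uses non-N bases as its denominator, which
avoids biasing the estimate near masked regions.

## GC correction

Coverage on Illumina instruments depends on local GC content. Each
bin's value is rescaled by the ratio of the global median to the median
of bins with similar GC:

$$\tilde r_i = \frac{n}{n_{GC}}\, r_i,$$

where "similar" means a GC fraction within 0.001 of bin *i*'s. The
correction is applied independently to RD and MQ. It is
scale-equivariant and, when the GC values fall into separated strata,
leaves every stratum with the same median as the whole profile. If some
stratum has median 0 the corrected value is set to 0 with a warning
rather than propagating an infinity.

## Total-variation denoising

Adjacent bins share biology but differ by sampling noise. Median or
linear smoothing would blur the one thing that matters — the sharp edge
at a duplication boundary — so both tracks are denoised with the
total-variation penalized least-squares model (the fused-lasso signal
approximator):

$$\min_a \tfrac12\lVert b-a\rVert_2^2 + \lambda\lVert Da\rVert_1$$

with $D$ the first-difference operator. The objective is strictly
convex; the package computes the **exact** minimizer with a direct
single-pass algorithm of the taut-string family rather than an
iterative scheme — deterministic output, no tolerance knob, O(n)
typical cost. At $\lambda = 0$ the input is returned unchanged; as
$\lambda \to \infty$ the solution approaches the constant mean; the
minimizer always conserves the mean of the input. The default
$\lambda = 0.25$ deliberately smooths only weakly; there is no reliable
automatic rule for choosing $\lambda$, so it is exposed to the user.

## Scale normalization

MAPQ values (0–60) are an order of magnitude larger than typical bin
depths, so a Euclidean distance in the raw plane would be dominated by
MQ. The MQ track is affinely mapped onto the RD range:

$$\widetilde{MQ} = \frac{MQ - MQ_{min}}{MQ_{max}-MQ_{min}}
  (RD_{max}-RD_{min}) + RD_{min}.$$

The map is monotone — ordering and distribution shape are untouched —
and the output range equals the RD range exactly. If all MQ values
coincide (e.g. a sample with uniformly confident alignments) the track
is mapped to the RD midpoint with a warning, which neutralizes MQ as a
feature instead of producing 0/0.

# Clustering

DBSCAN with Euclidean distance runs over the (smoothed RD, normalized
smoothed MQ) points of the valid bins. A point whose closed
ε-neighborhood (the point itself counts) holds at least `minPts` points
is a core point; clusters are density-connected components of core
points; non-core points within ε of a cluster become border members;
everything else is noise. Defaults: `eps = 0.7` and `minPts = 4` (twice
the number of features). Note that ε is an absolute radius in the
normalized feature space: it presumes this package's exact
preprocessing, and nothing here claims 0.7 is optimal under a different
normalization.

Neighborhood queries go through an exact 2D k-d tree ("2D BST"):
alternating-axis lower-median splits starting on the MQ axis, leaf
buckets of at most 16 points, and backtracking range search that visits
a sibling subtree only when the splitting hyperplane lies within ε of
the query — the exact condition under which the sibling can contain a
qualifying point. The result is identical to an exhaustive scan (this
identity is asserted against a brute-force oracle in the test suite);
only the number of distance evaluations changes.

Determinism choices, made once: the neighborhood ball is closed
(distance exactly ε qualifies); even-sized median splits take the lower
median; cluster seeds are expanded in ascending bin index, so a border
point reachable from two clusters joins the first one to reach it. The
noise set — the output that matters here — is independent of all these
tie-breaks and of point order.

# From noise bins to calls

Maximal runs of consecutive noise bins become rough regions; runs
separated only by invalid (N-filtered) bins are still merged by default,
because an N gap in the reference should not split one duplication event
in two (configurable). For refinement, the caller collects split
signals over the extended region `[a - searchPad, b + searchPad]`
(default pad: one bin): post-alignment positions within
`[a - searchPad, b]` vote for the low boundary, pre-alignment implied
ends within `[a, b + searchPad]` for the high boundary. Searching the
whole extended region, not just a window around each edge, was a
deliberate choice: a rough region occasionally over-extends by one bin
(an adjacent bin drifts into noise), and with a per-edge window the
true junction cluster — which always sits *inside* the extended region
— would then be missed. Since every copy junction of a TD produces
clips at the same two breakpoints, votes concentrate exactly there. The
candidate with the most support wins; ties go to the candidate closest
to the rough boundary, then to the smaller coordinate. A side with no
candidate keeps its bin-resolution coordinate (support 0). A refined
boundary never leaves `[a - searchPad, b + searchPad]`.

DBSCAN noise is sign-agnostic — a deletion depresses depth the same way
a duplication raises it — so an optional filter (`dupFilter`) can drop
regions whose mean smoothed depth does not exceed the genome median. It
is off by default: the method's stated behavior is that every noise
region is reported.

Clipped reads are required for refinement: on data whose aligner
records no clips, calls stay at bin resolution (stage `"rough"`), which
is a documented limitation of the split-read strategy.

# Parameters

| name | default | unit | meaning |
|------|---------|------|---------|
| `lenBin` | 2000 | bp | bin width; resolution/noise trade-off of stage one |
| `lam` | 0.25 | signal units | TV penalty; larger flattens more |
| `eps` | 0.7 | normalized feature units | DBSCAN radius |
| `minPts` | 4 | points | core-point threshold (2 × number of features) |
| `gcWindow` | 0.001 | GC fraction | GC-stratum half-width |
| `searchPad` | `lenBin` | bp | split-read search slack around a rough region |
| `minClipLen` | 10 | bp | shorter clips are sequencing-error dominated |
| `dupFilter` | off | — | drop regions at or below median depth |
| `poolGenome` | off | — | cluster all chromosomes jointly instead of per chromosome |

Clustering runs per chromosome by default — depth and MQ baselines are
chromosome-local, and it keeps memory bounded; `poolGenome = TRUE`
offers the joint alternative.

# The simulator

`simulateSample()` generates the full benchmark fixture: an i.i.d.
reference with configurable GC (and optional N runs), a donor genome in
which each embedded segment is followed immediately by `k` extra tandem
copies, and a coordinate-sorted indexed BAM rendered *analytically* —
read placements are drawn uniformly from a donor/reference mixture
(fraction `purity` from the donor, emulating tumor purity), and each
donor read's reference alignment is computed from the donor-to-reference
block map instead of running an aligner. Reads inside extra copies map
back onto the source segment, raising its apparent depth; reads spanning
a copy junction are emitted with the correct `yM(L-y)S` or `xS(L-x)M`
CIGAR anchored at the true breakpoint, the matched side being the longer
fragment (ties go to the match-first shape). MAPQ is 60 outside
duplicated spans; donor-origin reads overlapping an embedded TD draw
MAPQ uniformly from 0–30, mimicking the degraded confidence the aligner
reports for multi-mapping reads. Reference-origin reads keep MAPQ 60
everywhere, so a purity-0 sample carries no TD signal at all — the
negative control the pipeline is tested against. Everything is
deterministic under one seed. A FASTQ escape hatch exists for users who
want to run a real aligner instead.

Benchmark-grade defaults are 10 TDs of 10–50 kb with 1–6 extra copies
at 30× coverage and purity 0.9 on a 5 Mb reference; the test suite and
the acceptance script run a desk-scale variant (2 Mb, 5 TDs of 2–10 kb,
same coverage/purity, 50 and 10 seeded replicates respectively), sizes
chosen so the whole suite re-runs in minutes while every stage still
sees realistic signal.

What the simulator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: sequencing errors beyond
an optional uniform substitution model, indels, chimeric or
paired-end artifacts, mappability structure and repeat-induced MAPQ
patterns outside the duplications, coverage waviness beyond sampling
noise, and aligner-specific clip placement heuristics. The MAPQ model
in particular encodes the *assumption* that aligners report depressed
confidence inside duplicated regions; on real data the strength of that
signal depends on the aligner and the repeat context, and detection
then leans correspondingly harder on depth.

# Evaluation utilities

A truth region counts as recovered when a single call covers at least
half of its length; matching is one-to-one and greedy by overlap width.
Sensitivity, precision and F1 follow the usual definitions with the
convention that an empty denominator yields 0 (keeps metrics
plottable). Boundary bias is the mean of
$(|\Delta start| + |\Delta end|)/2$ over matched pairs — `NA` when
nothing matched, since an unmatched call set has no boundaries to
measure. For real samples without truth, the overlap density score
compares methods against each other: $ODS = M_{overlap}^2/N_{called}$,
with $M_{overlap}$ the mean (over the other methods) count of a
method's calls that are half-covered by the other method's calls — the
mean-over-other-methods reading of the average. The permutation test
uses $s = |\bar X - \bar Y|$ and reports the fraction of label
permutations with statistic strictly larger than $s$.

# Numerical and design notes

* **Coordinates.** In memory everything is 1-based inclusive
  (`GRanges`/`IRanges`, the native Bioconductor convention — SAM
  positions and the `b = pos + y - 1` rule translate directly); BED
  files are written and read as 0-based half-open at the boundary.
* **TV solver.** Exact direct algorithm; the test suite certifies it to
  1e-6 against an independent quadratic-programming oracle that solves
  the dual box-constrained QP (on 200 random signals it agrees to
  ~1e-12).
* **Degenerate inputs.** Constant MQ → RD-midpoint mapping with a
  warning; zero-median GC strata → corrected value 0 with a warning;
  `lenBin` longer than the chromosome → single bin with a warning; a
  refinement that would invert a region (start ≥ end) is rejected and
  the rough coordinates kept.
* **Low-quality reads** are kept on purpose (their depletion of MQ is
  signal); duplicate-flagged, secondary and supplementary records are
  skipped because they would double-count coverage.

# Limitations

TD candidates are whatever DBSCAN refuses to cluster, so any bin-level
outlier — including deletions or copy-neutral MQ anomalies — can
surface as a rough region unless `dupFilter` is enabled. Very long,
high-copy duplications can flatten into a dense feature clump of their
own and be claimed as a cluster rather than noise, splitting or hiding
the event; ε would need retuning for such regimes. Copy counts are not
estimated, inter-chromosomal events are out of scope, and refinement
requires clip-bearing alignments.
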