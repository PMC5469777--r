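---
title: "Methods: read-depth CNV analysis of shallow WGS from few-cell WGA samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNV analysis of shallow WGS from few-cell WGA samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowCNV)
```

## The problem

Copy-number profiling of one or a few cells requires whole-genome
amplification (WGA) before sequencing, and WGA over- or under-amplifies
loci unpredictably. At shallow sequencing depth (~0.3x) the read count per
fixed-size genomic window is the CNV signal, so this *representation bias*
is the factor that limits resolution — not depth. `shallowCNV` implements
the complete read-depth analysis for this setting, plus a simulator that
generates per-window counts with exactly the statistical structure the
analysis assumes, so every stage can be validated end to end without
sequencing data.

## The count model

For window $w$ of width $L_w$, at mean fold-coverage $d$ with read length
$\ell$ and window copy number $C_w$ (length-weighted over the window), the
simulator draws

$$x_w \sim \mathrm{Poisson}\!\left(\frac{d\,L_w}{\ell}\cdot\frac{C_w}{2}
  \cdot b_w \cdot g(\mathrm{gc}_w)\right),
  \qquad b_w = e^{z_w},\; z_w \sim N(0, \sigma_n^2),$$

independently per window. At the study conditions — $d = 0.3$,
$\ell = 75$ bp, $L_w = 1$ Mb — a diploid window expects 4000 reads.

* **Amplification bias** is a window-independent multiplicative log-normal
  factor. The bias of real WGA chemistries is locus-correlated; an
  independent per-window factor is the minimal model that reproduces the
  per-window variance statistic the analysis measures, and it is the
  regime the pipeline's guarantees are stated for (see *Limitations*).
* **Cell-number attenuation**: $\sigma_n = \sigma\,a^{\,n-1}$ for $n$ input
  cells, with attenuation $a = 0.85$ by default. Pooling cells averages
  independent amplification trajectories, and multi-cell samples show
  slightly lower read-count variance than single cells.
* **GC response** $g(\mathrm{gc}) = 1 + c_1(\mathrm{gc}-0.4) +
  c_2(\mathrm{gc}-0.4)^2$, mean-normalized over the grid. Defaults
  $c_1 = c_2 = 0$: GC correction is exercised by tests that inject a
  response explicitly, never implicitly.
* **Poisson, not negative-binomial** sampling: overdispersion is already
  carried by the log-normal bias layer, so a second dispersion parameter
  would be unidentifiable here.
* Per-method bias magnitudes are free parameters (the source study shows
  variances only graphically); the default cohort design uses
  $\sigma \in [0.07, 0.11]$ across the four method labels. These are
  plausibility choices, not calibrated claims.

Cohorts derive one sub-seed per sample from the master seed and the
sample's (method, cell count, replicate) identity through a Lehmer-style
modular hash, so any sample can be regenerated in isolation.

## Windows, annotation, masking

Coordinates are 0-based half-open (BED convention) throughout. Windows
tile each chromosome at a configurable size (1 Mb and 500 kb are the two
sizes of interest); the terminal window is truncated at the chromosome
end. A window is *usable* unless

* it is blacklisted — the union of user-supplied blacklist intervals
  covers at least `blacklist_overlap_fraction` (default 0.5) of it; or
* it is a terminal window shorter than half a window, whose count is not
  comparable to full windows.

Unusable windows still receive simulated counts and still appear in every
serialized track; they are excluded from median estimation, from the
variance statistic, and from segmentation, and their bp span is absorbed
by the flanking segments. The built-in blacklist handling accepts any BED
file; no external annotation is downloaded.

## Normalization and copy-number estimation

1. **GC/mappability correction.** Two sequential stratified-median
   corrections: windows are binned by GC (width 0.05) and the per-bin
   factor is the bin's median count over the global median; factors are
   linearly interpolated between the bins' median GC values (and linearly
   extrapolated beyond the outermost bins) so a smooth trend is removed
   without leaving within-bin residual structure. The same procedure then
   runs along mappability (bin width 0.1). Bins with fewer than 20 usable
   windows do not form interpolation nodes. A median-based stratified
   estimator was chosen over 2-D loess for determinism and testability;
   on discrete covariate strata it reduces exactly to classical
   stratified-median scaling.
2. **Median normalization.** Each corrected count is divided by $a$, the
   median count over usable windows. Aberrations are assumed rare, so $a$
   estimates the diploid expectation and ratios measure deviation from
   diploidy.
3. **CN estimate.** $\mathrm{CN}_w = 2\,x_w/a$ and
   $\log_2(\mathrm{CN}_w/2)$. Zero-count windows keep ratio 0 and a log2
   floor of $-4$ (configurable) instead of $-\infty$.

All medians use the lower-median convention (the smaller central order
statistic for even counts): results are deterministic, and the window
attaining the median gets ratio exactly 1, which makes the invariant
"median of usable ratios equals 1" exact rather than approximate.

## The read-count variance statistic and the quality gate

Per sample the pipeline computes

$$V = \frac{1}{N}\sum_{i=1}^{N-1}
  \left(\frac{x_i}{a} - \frac{x_{i+1}}{a}\right)^2,$$

with $N$ the number of usable windows in genome order and $a$ the median
count. Scaling by $a$ makes $V$ invariant to total read count. Pairs are
formed between consecutive usable windows — a masked window is skipped
and its neighbors pair directly — and, because the study does not state
whether adjacency crosses chromosomes, pairs break at chromosome
boundaries by default (`across_chromosomes = TRUE` restores the
alternative). Division is by $N$ as the formula states, not $N - 1$. For
a pure-Poisson diploid track $V \to 2/a$; amplification bias adds
$\approx 2\,\mathrm{Var}(b)$ on top.

Samples with $V$ strictly above `quality_cutoff` (default 0.1, roughly
50x the Poisson floor at 4000-count depth) are flagged *failed* and carry
no calls, emulating the study's manual exclusion of profiles too
irregular to interpret. The numeric cutoff is a heuristic encoding of a
visual judgement and is deliberately configurable; a simulated failure at
$\sigma = 1.5$ exceeds it by three orders of magnitude, so the gate is
insensitive to its exact value in that regime.

## Circular binary segmentation

Per chromosome, the log2 ratios of usable windows are segmented
recursively:

1. **Arc scan.** All circular arcs $(i, j)$ whose length and complement
   both hold at least `min_seg_windows` (default 2) windows are scanned
   for the maximal pooled-variance two-sample $|t|$ between the arc and
   its complement (the complement of an interior arc wraps around). The
   scan is exhaustive and $O(n^2)$, acceptable at the few thousand
   windows of these grids, and implemented in C++. When the pooled
   variance is zero the statistic is 0 for equal means and a $\pm 10^{12}$
   surrogate otherwise. Maxima are ordered by $|t|$, then by signed $t$,
   then by smallest $i$, then $j$ — tied maxima are complementary
   boundary arcs describing the same split, so the tie-break never
   changes the partition.
2. **Permutation test.** The split is accepted when
   $p = (1 + \#\{\text{perm max}\,|t| \ge \text{observed}\})/(1 + n_{\mathrm{perm}})
   < \alpha$, with $n_{\mathrm{perm}} = 1000$ and $\alpha = 0.01$
   (common CBS practice; both configurable). The add-one estimator avoids
   $p = 0$. Shuffles use a self-contained mt19937 Fisher-Yates so results
   are identical across platforms; inside the recursion the loop stops
   early once enough exceedances guarantee $p \ge \alpha$, which cannot
   change any split decision. Child calls derive sub-seeds from the
   parent seed, recursion depth and cut positions.
3. **Merging.** Adjacent segments whose pooled two-sample t-test p-value
   is at least `merge_alpha` (default 0.05) are merged; two single-window
   segments (zero degrees of freedom) cannot be tested and merge.

Segmentation and segment means operate on log2 ratios (the convention of
window-based CNV callers); the alternative of averaging raw counts gives
the same breakpoints on these tracks but less interpretable segment
levels.

## Calling, detection limit, evaluation

A segment is called when $|\overline{\log_2}| > 0.35$ — *strictly*, so a
segment at exactly the threshold is not called — and it spans at least 3
windows. The threshold corresponds to CN above $2 \cdot 2^{0.35} \approx
2.55$ or below $2 \cdot 2^{-0.35} \approx 1.57$; the window rule gives a
detection limit of `min_windows * window_size` (3 Mb at 1 Mb windows,
1.5 Mb at 500 kb). Same-direction calls separated by a sub-threshold gap
are not merged: the reference genome itself contains two deletions
separated by a 2.5 Mb diploid gap, and that gap is biology, not noise.

Calls are scored against a reference karyotype by greedy one-to-one
matching in genome order: same chromosome, same direction, and overlap
(after relaxing the call's endpoints by one window) of at least 50% of
*both* the call and the event length. The reciprocal-overlap rule and
tolerance follow CNV-benchmarking convention and are configurable because
the source study states none; direction agreement is required even though
the study leaves it implicit. One consequence of one-to-one matching is
documented bias: a single call spanning two reference events scores one
TP and one FN.

Method groups are compared with a classical one-way fixed-effects ANOVA
on the per-sample variance statistic (significance at 0.05), computed
from sums of squares and cross-checked in the tests against `lm()`.

## The built-in reference karyotype

`loucy_fixture()` places the reference aneuploidies of the Loucy
lymphoblastoid line — deletions of 6, 36.5 and 30 Mb on chromosome 5
(the first two separated by a 2.5 Mb diploid gap), 60 Mb on chromosome 6,
3 Mb on chromosome 12, 16 and 3 Mb on chromosome 16, a 26 Mb duplication
on chromosome 13 and loss of the whole X — on a synthetic eight-chromosome
layout with round coordinates (chromosomes 2 and 7 are copy-neutral).
Cytoband-accurate placement is irrelevant to the read-depth computation,
and the genome build underlying the original array coordinates is not
stated, so the fixture deliberately abstracts positions while preserving
every event length. `scale` shrinks all coordinates for fast tests.

## What the tests show — and what they cannot

The test suite runs the full pipeline on simulated cohorts: at 1 Mb
windows and $\sigma = 0.05$ every fixture event is recovered with zero
false positives in 20 of 20 seeded runs, and the chromosome-13 gain and
chromosome-6 loss lengths are recovered to the window. Calibration checks
confirm the ANOVA type-I error (~5% over 1000 replicates) and a CBS
false-split rate on pure-noise chromosomes at or below about twice the
split level. Monotonicity checks confirm that sensitivity falls and
false positives rise with $\sigma$, and that the variance statistic falls
with cell number.

Problem sizes were chosen so the suite exercises realistic geometry at
desk scale: the full 1240-window genome at 1 Mb for recovery checks,
10–20x shrunken genomes with proportionally smaller windows for cohort
bookkeeping, and 200–1000 permutations depending on what the test
measures.

None of this validates the pipeline on real WGA sequencing data. The
simulator omits locus-correlated amplification bias, allele dropout,
chimeric fragments, mappability structure of a real reference, and
mosaicism between cells; per-sample results from the study's sequencing
runs (mapping rates, per-sample TP/FP tables, per-method variance
boxplots) depend on the deposited reads and are out of scope. Passing
tests show the algorithmic chain is correct under its own model, with
calibrated statistics — not that any particular WGA chemistry performs as
simulated.

## Known limitations

* Independent per-window bias understates the spatial correlation of real
  WGA bias; real profiles need wider windows than the simulator suggests
  for the same nominal $\sigma$.
* The quality gate is a single global cutoff; a sample with severe *local*
  bias can pass it, which mirrors the known weakness of the genome-wide
  variance metric.
* The $O(n^2)$ arc scan is intended for window counts up to a few
  thousand; hybrid CBS pruning would be needed well beyond that.
* No sex-chromosome baseline adjustment and no mosaicism-aware fractional
  calling.
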