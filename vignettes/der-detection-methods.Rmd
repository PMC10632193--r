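---
title: "Annotation-free detection of differentially expressed regions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-free detection of differentially expressed regions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derseg)
```

## The problem

Classical differential expression analysis counts reads over annotated
features and therefore cannot see what the annotation does not describe:
5' and 3' extensions, retained introns, antisense transcripts, processing
intermediates. `derseg` takes the *identify-then-annotate* route instead:
it discovers the boundaries of differentially expressed regions (DERs)
directly from the per-base signal of a two-condition stranded RNA-seq
experiment, and only afterwards relates them to an annotation.

## The signal: per-base log2 fold-change

For replicate $r$ of condition $j$, a per-base coverage $Q_{ijr}$ is built
over the analysed window, separately per strand. Four summaries are
available; the default combines the 5'-end count $Q^{5'}$ and the 3'-end
count $Q^{3'}$ through a geometric mean on the +1 scale,

$$Q_{ijr} + 1 = \sqrt{(Q^{5'}_{ijr} + 1)(Q^{3'}_{ijr} + 1)},$$

which responds to both transcript ends while staying integer-equal to
either end profile when the two agree. Full-length coverage and each end
alone are selectable alternatives (`mode` argument). The segmented signal
is the replicate-averaged per-base log2 fold-change

$$Y_i = \frac{1}{R_1}\sum_{r=1}^{R_1}\log_2(Q_{i1r}+1)
      - \frac{1}{R_2}\sum_{r=1}^{R_2}\log_2(Q_{i2r}+1),$$

with condition 2 the user-designated reference (denominator). $Y$ scales
with the local intensity of the transcriptional difference and is the
natural input for changepoint detection.

Library-size normalization shifts $Y$ by the constant
$\rho = \overline{\log_2 s_{1r}} - \overline{\log_2 s_{2r}}$ built from the
sample size factors. Because the segmentation below is shift invariant,
changepoint positions do not depend on $\rho$, so no per-base normalization
of $Y$ is needed (the argument is exact for the count model and approximate
at very small counts, where the $+1$ offsets bite). $\rho$ is reported on
the fitted object for interpretation.

## The segmentation model

Within a segment the $Y_i$ are modelled iid Gaussian with a segment mean
$\mu_j$ and a common variance $\sigma^2$; changepoints are shifts of the
mean. The estimate is the global minimizer of the penalized least-squares
criterion

$$\sum_j \sum_{i \in \text{seg}_j} (Y_i - \mu_j)^2 + D\,\beta,
  \qquad \beta = \lambda\,\hat\sigma^2\,\log n,$$

over *all* segmentations, solved exactly by functional-pruning optimal
partitioning (FPOP): the optimal cost as a function of the last segment's
mean is a piecewise quadratic, updated point by point with a Viterbi-style
recursion and interval pruning, then backtracked. The solver is compiled
and handles signals of $10^6$–$10^7$ bases in seconds. Two independent
oracles guard it in the test suite: the classical $O(n^2)$ optimal
partitioning recursion, and exhaustive enumeration of all $2^{n-1}$
segmentations for tiny $n$.

Numerical and tie-breaking choices:

* a changepoint is introduced only on a strict cost improvement, and among
  equal-cost locations the earliest wins — deterministic, parsimony-first
  output;
* envelope roots are computed from discriminants and candidate intervals
  narrower than $10^{-12}$ are merged, keeping the recursion stable in
  floating point (it is exact in exact arithmetic);
* $n = 1$ returns the trivial segmentation; $\beta = 0$ returns the
  minimal-cost maximal segmentation consistent with the tie-break; constant
  profiles return one segment with a warning, without estimating a
  penalty.

Open choices we fixed: the penalty uses the natural logarithm (the base is
absorbed by $\lambda$, and `log_base` is an argument); $\hat\sigma^2$ is the
unbiased sample variance of $Y$ estimated per strand over the whole window,
as the model states, even though $Y$ contains signal — a first-difference
estimator that ignores piecewise-constant signal is available behind
`var_estimator = "difference"`. The default $\lambda = 2$ follows the
theory-backed recommendation for this penalty family; larger $\lambda$
gives coarser segmentations.

## Per-segment testing

Reads are assigned to every segment they overlap by at least one base on
the segment's strand (a boundary-spanning read counts in each neighbour;
`multi_overlap = FALSE` assigns to the largest overlap instead). The
segments-by-samples count matrix is tested with a two-group
negative-binomial model, variance $\mu + \alpha\mu^2$:

* **size factors** — median-of-ratios to the per-segment geometric mean,
  rescaled to geometric mean 1. Because segments have very unequal lengths
  and a handful of them can carry most of the differential signal, the
  median is weighted by segment width inside the pipeline, so each *base*
  of the window contributes equally. The estimator still assumes that most
  of the window is not differential; a window consisting almost entirely
  of one strong DER will bias the factors, as any global normalization
  would.
* **dispersion** — per-segment Cox–Reid-adjusted profile likelihood for
  the two-group model. At typical replication (2–5 per group) the
  per-segment likelihood scatters widely below the truth, which would make
  the Wald test anti-conservative, so estimates falling below a fitted
  mean-dispersion trend $a_0 + a_1/\bar\mu$ are floored at the trend;
  above-trend estimates are kept. No other shrinkage, no independent
  filtering, no outlier replacement: the two-group design does not need
  the heavier machinery, and each simplification is named and tested
  (null p-values stay near uniform, and point estimates agree with an
  established NB reference implementation in the test suite).
* **Wald test** — log-link GLM with `log(size factor)` offsets; the group
  contrast on the log2 scale against the standard normal. A group with all
  zeros is fitted at the parameter floor without pseudocounts and flagged
  `boundary`; the p-value remains defined.
* **multiplicity** — Benjamini–Hochberg across all tested segments, both
  strands pooled into a single family (one experiment, one family);
  all-zero segments are untestable and excluded from the family size.

## DER calling with a post-hoc FDP guarantee

BH controls the *expected* false discovery proportion, but any further
selection (for example by fold change) voids that guarantee. The package
therefore reports a post-hoc bound valid for arbitrary selections, built
from the Simes reference family with thresholds $t_k = \alpha k / m$
($m$ = number of tested segments): for a selection $S$,

$$\bar V(S) = \min_{1 \le k \le |S|}
  \bigl(\#\{i \in S : p_i \ge t_k\} + k - 1\bigr)$$

upper-bounds the number of false discoveries in $S$ with probability
$1-\alpha$, and $\bar V(S)/|S|$ bounds the FDP. DERs are the largest set of
segments with fold change above 1.5 (or below 2/3) whose bound stays at or
under the 5% target. "Largest" is operationalized as the longest prefix of
the candidates ordered by increasing p-value (ties broken by genomic
start), every prefix being checked explicitly — deterministic and
order-invariant. The parametric Simes thresholds are used as is;
permutation-based joint-error-rate calibration is a possible extension and
is not implemented.

## Annotation labels

Each DER is labelled against its minimal-distance annotation(s) (strand
ignored for the nearest search; distance ties produce one label each) with
seven mutually exclusive classes: `inside`, `overlapping_5prime`,
`overlapping_3prime`, `overlapping_both` (strand-aware boundary crossings;
a shared endpoint does not cross), `antisense` (opposite-strand overlap —
antisense takes precedence over the positional classes), `upstream` and
`downstream` (no overlap, sides taken on the annotation's strand, with a
`strand_mismatch` flag for opposite-strand neighbours).

## What the synthetic data emulates — and what it does not

The generator plants piecewise-constant log2 fold-changes into per-base
5'-end intensities on both strands, draws NB replicate counts
(`dispersion = 0` gives Poisson), and realizes them as sorted, indexed
BAMs of constant-length single-end reads whose 5'-end coverage equals the
drawn counts *exactly*; the 3'-end profile is then the 5'-end profile
shifted by `read_length - 1`, so the geometric coverage mode is exercised
non-trivially. Consequences worth knowing:

* in geometric mode a planted boundary at $a$ produces *two* noiseless
  changepoints, at $a$ and at its read-length-shifted copy, separated by a
  half-effect plateau; boundary-accuracy evaluations compare against this
  expected changepoint set;
* blank designs (same-condition replicates split into two artificial
  groups) make every called DER a false positive by construction and are
  enumerated exhaustively or subsampled reproducibly.

Defaults mirror a deep bacterial/organellar RNA-seq setting: baseline
5'-end intensity 20 per base (deep chloroplast libraries reach several
times that), NB dispersion 0.05, 50 nt reads, two to five replicates per
condition. Not modelled: sequencing error, GC and positional bias,
fragment-length variation, paired-end synthesis (the paired-end code path
is tested on small hand-written alignments), multi-mapping ambiguity.
Passing tests on this generator show the statistical machinery behaves as
designed — they do not certify performance on real libraries, whose
coverage is far less homogeneous.

## Problem sizes used in the checks

The shipped verification suite uses: 200 random signals (n up to 200)
against the quadratic-time oracle plus exhaustive enumeration up to n = 12;
a 10 kb window with three planted DERs (effects +1, −1, +2, 2 vs 2
replicates) across 10 seeds for recovery and ±10 bp boundary accuracy; 50
blank 2 vs 2 designs from ten replicates over 5 kb; 500 simulated count
datasets for the post-hoc bound and BH control; a 500-segment 3 vs 3 null
for p-value calibration (the Kolmogorov–Smirnov tolerance of 0.12 was
frozen from a one-off calibration study at these settings, where observed
distances centre near 0.06); and a single 10^6-base profile as a
throughput smoke test. These sizes were chosen so the whole suite runs
comfortably on a laptop-class single core.

## Known limitations

* The Gaussian homoscedastic model for $Y$ is an approximation; counts
  near zero make $Y$ discrete and its variance position-dependent. The
  penalty absorbs much of this in practice, and the variance estimator can
  be switched to the difference-based form when strong signal inflates the
  sample variance.
* One scalar size factor per sample cannot express composition changes;
  windows dominated by differential signal bias normalization.
* The per-segment fold-change filter uses the unshrunk estimate; very low
  counts can pass the filter with wide intervals (the FDP bound, not the
  filter, is the guarantee).
* `m` in the Simes thresholds is the number of tested segments of the
  analysis at hand; analysing many windows separately and pooling their
  DERs afterwards voids the bound.
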