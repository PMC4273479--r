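---
title: "Models and methods behind aluscancnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aluscancnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluscancnv)
library(dplyr)
```

## The problem

Inter-Alu PCR capture sequencing amplifies the genomic neighborhoods of Alu
repeats and sequences the amplicons. It needs only sub-microgram DNA, which
makes large sample collections practical, but the resulting coverage is
unlike whole-genome data: most fixed-size genome windows receive no reads at
all, covered windows receive counts that depend on capture efficiency and GC
content, and the covered set itself depends on the primers used. CNV callers
built for continuous whole-genome or fixed-target exome coverage transfer
poorly to this regime. `aluscancnv` implements a window-level read-depth
pipeline designed for it, in three stages plus a classification layer:

1. **Localized calls** — per-window gain/loss tests on read-depth ratios via
   the Geary-Hinkley transformation (GHT);
2. **Recurrent calls** — cohort-level identification of windows whose CNV
   frequency exceeds an exact Poisson-binomial tail cutoff;
3. **Extended calls** — multi-window segments from circular binary
   segmentation (CBS) of GC-corrected, standardized log-ratios;
4. **CNV-feature classification** — correlation-based feature selection and
   naive Bayes cross-validation on binary CNV matrices.

## Depth model and windowing

The genome is tiled into contiguous windows (0-based, half-open BED
coordinates); 5 kb is the base size, and coarser tilings (100/300/500 kb) are
formed by summing base windows with `merge_windows()`, which conserves the
read total exactly. The read depth `R` of a window is the number of read 5'
starts falling in it and is modeled as Poisson with rate `lambda`. Counting
starts rather than per-base coverage keeps the count model exact; one read
contributes to exactly one window.

Because capture hot-spots produce extreme outlier windows, each profile is
winsorized before analysis: depths above the 95% quantile of the
*positive*-depth distribution are capped at that quantile (linear
interpolation between order statistics). The zero-inflated nature of the data
is why the quantile is taken over covered windows only; including the zeros
would push the cap far into the informative range. Winsorization is applied
at the base window size, before merging, and is idempotent.

A paired control can be replaced by a **reference template**: the per-window
integer sum of depths over a set of reference samples. Sums of independent
Poisson counts are Poisson, so the template behaves statistically like a
deeply sequenced control. Pooling is exact integer arithmetic.

Only windows with strictly positive depth in both the test sample and the
control/template are analyzed; a zero on either side leaves the depth ratio
undefined and carries no information under this model.

## Localized calling (GHT)

For an analysis window with depths `R_t`, `R_c` and sample totals `N_t`,
`N_c`, the adjusted ratio is

    r = (R_t / R_c) * (N_c / N_t)

At sufficiently high rates, the Poisson counts are approximately normal with
variance equal to the mean, and the Geary-Hinkley transformation converts the
ratio into an approximately standard-normal statistic

    t = (lambda_c * r - lambda_t) / sqrt(lambda_c * r^2 + lambda_t)

where `lambda_t`, `lambda_c` are the mean depths over the analyzed windows.
The two-sided p-value is `2 * (1 - Phi(t))` for `r > 1` and `2 * Phi(t)` for
`r < 1`; `r = 1` is neutral by definition (`p = 1`). A window is a gain when
`p < alpha` and `r > 1`, a loss when `p < alpha` and `r < 1` (default
`alpha = 0.05`, no multiple-testing correction at this stage). For GC-aware
calling the windows are stratified into twenty 5%-wide GC groups and the rate
parameters are estimated per group over the analysis set of the comparison;
groups with fewer than 30 analysis windows (configurable) fall back to the
global rates with a warning, because near-empty groups give unstable means.

The normal approximation degrades at low rates. The package's own
calibration (run in the test suite at 100,000 windows) shows that at
`lambda = 100` the statistic has mean ~0 and standard deviation ~0.995, and
the null non-neutral call rate is ~0.0484 against the nominal 0.05 — slightly
conservative, which we consider acceptable; as a working rule we recommend
window sizes large enough to give mean depths of at least ~50. Windows-size
defaults follow this logic: coarse (500 kb) windows for localized calling on
sparse cancer scans, fine (5 kb) windows as segmentation input.

## Recurrent calling (Poisson binomial)

Given localized calls for a cohort of `n` samples, a binary matrix `M` is
built per state (gains and losses separately) over the windows analyzable in
*every* sample. Under the assumption that copy-number alterations arise
independently across samples, the count `K` of samples carrying a CNV at a
window is a sum of independent Bernoulli trials with per-sample rates `p_j`
(estimated as column means of `M`). Its exact distribution — the Poisson
binomial — is computed by iterative convolution: `O(n^2)` time, exact and
stable to cohort scale (the test suite checks agreement with exhaustive
enumeration to 1e-12 for n <= 12 and unit normalization at n = 1000). The
recurrence cutoff `k*` is the smallest count whose upper-tail probability
falls below 0.01, and windows with row sums at or above `k*` are flagged. A
Bonferroni option (`alpha / m`) is provided but off by default, since the
plain `p < 0.01` tail rule is the primary criterion.

## Extended calling (GC correction, Z scores, CBS)

Each sample's depths are first GC-corrected by the median-ratio rule

    D_corrected = D_global * D_raw / D_GC

with `D_global` the sample's median depth over analyzed windows and `D_GC`
the median of the window's 5%-GC group. The corrected ratio
`r = D_t_corrected / D_c_corrected` is log-transformed and standardized into

    Z = (ln r - mean ln r) / sd(ln r)

using the sample (n-1) standard deviation over all analyzed windows of the
test sample. A high Pearson correlation between test and control depths is a
useful prerequisite for meaningful segmentation; `call_extended()` emits it
as a QC metric and warns below a configurable threshold (default 0.8).

Each chromosome's Z vector is then segmented by circular binary
segmentation: the scan maximizes, over all boundary pairs `(i, j)` of the
circularized window sequence, the absolute difference between the arc mean
and the complement mean scaled by `sqrt(l * (n - l) / n)` and the
segment-global standard deviation. A split is accepted when its permutation
p-value is below `alpha = 0.01`, and the accepted arc boundaries partition
the segment, recursively, until nothing splits. Two numerical notes:

* The pooled-variance two-sample t statistic is a strictly monotone
  transform of this scan statistic for fixed data (the total sum of squares
  is constant), so both the split location and the permutation decision are
  identical whichever form is maximized; we scan the cheaper one.
* The permutation test (default cap 10,000 permutations) uses sequential
  early stopping: it stops "not significant" as soon as the exceedance count
  already guarantees `p >= alpha`, and stops "significant" at a block
  boundary once the observed exceedance count would itself be a < 0.1%
  probability event if the true exceedance rate were `alpha`. This keeps
  deep recursions fast while leaving the accept/reject behavior essentially
  unchanged; with a fixed seed the whole segmentation is deterministic.

Segments are classified by their mean Z: gain at `Z >= 0.2`, loss at
`Z <= -0.2` (both inclusive), neutral otherwise. The threshold is
deliberately permissive — extended CNVs are meant as large-scale summaries,
not per-window significance statements.

Boundary precision has intrinsic limits: with a +3-sigma shift of width 20
in 1,000 unit-noise windows, both breakpoints land within one window of the
truth in roughly 90% of runs; the misses place one boundary two to three
windows off. This is a property of the max-statistic itself (see the
monotone-transform note above), so no variant of the t-statistic scan can
improve it.

## CNV-feature classification

Binary CNV matrices (samples x windows) are reduced to a discriminative
subset by correlation-based feature selection: the merit of a subset of `k`
features is

    merit = k * mean(SU(f, class)) / sqrt(k + k * (k - 1) * mean(SU(f, f')))

with symmetrical uncertainty `SU = 2 I(X;Y) / (H(X) + H(Y))` as the
correlation measure on binary variables. Subsets are explored by best-first
forward search terminating after five consecutive non-improving expansions,
with deterministic index-order tie-breaks. The selected subset is evaluated
by repeated stratified two-fold cross-validation (default 1,000 iterations)
with a Laplace-smoothed naive Bayes classifier; AUC is the Mann-Whitney rank
statistic of the pooled held-out posteriors per iteration, averaged over
iterations (an aggregation we fixed by choice, as only the iteration scheme
is standard), and the F-score `2TP / (2TP + FP + FN)` is computed from
confusion counts pooled over all iterations. Hierarchical clustering uses
Euclidean distance with classic unsquared Ward linkage (`ward.D`), and node
support is the plain bootstrap proportion over feature-resampled trees —
deliberately simpler than multiscale "approximately unbiased" probabilities,
and interpreted accordingly.

A behavior worth knowing: CFS's redundancy penalty prefers small
non-redundant subsets. When a cohort carries many strongly class-associated
windows that are mutually correlated through the class, the merit-optimal
subset at small sample sizes (tens of samples) typically retains only part
of them — about half in our 40-sample simulations — while classification
accuracy from the retained subset remains essentially perfect. With
thousands of samples the same search recovers the full injected set. Feature
*recovery* and classification *performance* are therefore different claims
at cohort sizes typical of this assay.

## The synthetic-data generator

All tests run on synthetic data with known truth. `simulate_profile()`
emulates the sparse capture regime: a random 30% of windows is covered
(`coverage_fraction = 0.3`), covered windows draw Poisson counts at
`base_lambda = 100` times a GC multiplier and a CNV fold; uncovered windows
are zero. The GC bias curve is a smooth unimodal multiplier peaking at GC
0.45 with range [0.5, 1.5] — chosen once as a realistic shape for
amplification efficiency, strong enough that uncorrected calling visibly
miscalibrates and grouped/median correction rescues it. `simulate_pair()`
shares one coverage mask between test and control (a shared capture design);
`simulate_cohort()` and `simulate_labeled_cohort()` generate binary CNV
matrices with injected recurrent or class-associated windows.

What the generator does *not* emulate: window-to-window capture-efficiency
variation shared between samples (real paired profiles correlate strongly
across windows; iid simulated profiles do not, so the QC correlation is only
exercised on constructed examples), primer-set differences between test and
reference, mappability structure, and read-level artifacts. Passing tests
therefore demonstrate the statistical machinery under its stated model, not
robustness to every failure mode of real capture data.

## Problem sizes and defaults used in the shipped checks

The packaged test suite calibrates the localized caller on 100,000 null
windows at `lambda = 100`, checks recurrence conservativeness on a
20,000 x 38 null cohort, validates the Poisson-binomial pmf exhaustively to
n = 12 and at n = 1,000, runs 100 seeded CBS recovery simulations at 1,000
windows each, and evaluates the classifier on a 40-sample, 2,010-window
cohort with 1,000 CV iterations. These sizes were chosen to make the
statistical assertions sharp while keeping a full run in the order of a
minute of CPU.

## Known limitations

* No integer copy-number estimation: states are gain/loss/neutral.
* The GHT stage applies no multiple-testing correction; downstream recurrent
  analysis is the intended aggregation step.
* CBS parameters (split alpha, permutation cap, minimum width) are package
  defaults, configurable but not derived from any external reference.
* Sex chromosomes and unplaced contigs are excluded by default from window
  tilings.
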