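---
title: "Scoring chromosomal instability from shallow whole-genome coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chromosomal instability from shallow whole-genome coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chromosomal instability (CIN) — an elevated rate of chromosome-level and
arm-level gains and losses — is common in invasive breast cancer and has
been linked to metastatic behaviour. Shallow (low-pass) whole-genome
sequencing at roughly 0.1–1× depth cannot call base-level variants, but
the number of fragments falling in a fixed genomic window is an
inexpensive proxy for local copy number. `cinscore` turns such binned
counts into a single genome-wide instability score and a High/Low label,
and provides the cohort-level statistics used to relate that label to
sentinel lymph node metastasis (SLNM).

The pipeline has four stages, each an exported function so every stage is
testable in isolation:

1. **Binning** (`make_bins`, `bin_coverage`): the genome is tiled into
   fixed-width, half-open bins (200 kb by default) and each aligned
   fragment is counted into the bin containing its midpoint.
2. **Normalization** (`build_control_panel`, `normalize_profile`): the
   tumor's per-bin count is standardized against a panel of diploid
   controls, `Z = (raw − mean_controls) / sd_controls`.
3. **Segmentation** (`segment_sample`): circular binary segmentation
   (CBS) partitions each chromosome's Z vector into runs of constant
   copy state; segment means above +3 are called gains, below −3 losses.
4. **Scoring** (`cin_score`, `classify_cin`, `call_arm_changes`): the
   CIN score sums, over aberrant segments, segment length times |mean Z|;
   a cohort-derived cutoff splits samples into CIN-High and CIN-Low.

## Normalization model and its assumptions

The Z-score uses the per-bin mean and *sample* (m−1) standard deviation
of the control panel; panels are often small, so the unbiased denominator
matters. Bins where the panel variance is exactly zero carry no
information about spread and are masked: they propagate as `NA`, are
excised before segmentation, and are excluded from arm-coverage
denominators. No GC-content or mappability correction is applied — raw
counts enter the standardization directly, so the control panel must be
sequenced and processed like the tumors. An optional total-count
rescaling (`rescale_depth`) is available for panels whose members differ
substantially in depth, but it is off by default because the
standardization as defined operates on raw coverage.

With a panel of m controls the null distribution of Z at one bin is
approximately t with m−1 degrees of freedom scaled by sqrt(1 + 1/m), not
standard normal: for m = 20 the expected fraction of diploid bins with
|Z| > 3 is ~0.9%, not 0.27%. The calibration checks in the test-suite
measure this fraction on tens of thousands of simulated bins so that the
Monte-Carlo error is small against the 1% bound they assert.

## Circular binary segmentation

Each chromosome's Z vector is treated as a circle. The core operation
(`best_circular_split`) scans every arc `[i, j)` — every circular
two-arc partition has a contiguous representative, so the scan covers the
circle — and maximizes the absolute pooled-variance two-sample
t-statistic between the arc and its complement. The scan is O(n²) with
prefix sums, implemented in C++. Split significance is assessed by a
permutation test: the best statistic of each whole-vector shuffle forms
the reference distribution, and `p = (1 + k) / (1 + N)` with k the
number of shuffles reaching the observed statistic (the add-one estimator
is never exactly zero and is unbiased against the permutation null).
A split is accepted when `p < alpha` (default 0.01, N = 10,000) and the
procedure recurses on the resulting linear pieces.

Numerical and procedural choices:

* **Minimum segment width** (default 3 bins) replaces the optional
  "undo splits" pruning found in some CBS implementations.
* **Degenerate arcs**: when a candidate split leaves zero pooled
  within-variance, the statistic is 0 if the arc means agree and +Inf
  otherwise; a constant vector therefore yields statistic 0 and no split.
* **Ties**: an arc starting at 0 and its complement describe the same
  partition; the scan keeps the first maximizer in row-major (i, j)
  order. Exact ties occur with probability zero for continuous data.
* **Early stopping**: inside the recursion the permutation loop stops as
  soon as the already-observed exceedances force `p >= alpha` at the
  configured N. The accept/reject decision is identical to the full run;
  only rejected splits stop early. The public `split_significance`
  always runs all N shuffles so the reported p-value is exactly the
  add-one estimator.
* **Seeding**: each chromosome derives its own seed from the sample-level
  seed, and each significance test inside a chromosome advances a
  counter, so results are reproducible and independent of evaluation
  order.
* The statistic is scale-equivariant, so breakpoints are invariant to a
  positive rescaling of Z.

## CIN score and classification

The score is `sum over aberrant segments of L × |mean Z|`. Two choices
deserve emphasis because the defining formula is ambiguous on both:

* **Magnitude, not signed Z.** Summing signed values would let deletions
  cancel amplifications, and an unstable genome with balanced gains and
  losses would score near zero. Losses therefore contribute |Z|.
* **Length unit.** L is measured in bins by default (one bin = one grid
  window; 200 kb on the default grid), with a megabase option. An
  absolute score — and any absolute cutoff, including the packaged
  reference cutoff `cin_threshold_reference = 13563` — is only meaningful
  relative to a stated unit, bin width, panel and parameter set. For
  that reason the reference cutoff is never applied to simulated
  cohorts; `run_cohort` always derives a cohort-specific Youden-optimal
  threshold from its own ROC curve.

Neutral segments contribute nothing: segment means in (−3, 3) are read
as diploid noise. The gain/loss cut is symmetric at ±3 with strict
inequalities; the one-sided reading of the ±3 rule (everything below +3
a deletion) would leave no neutral state and is rejected. Classification
against a threshold is likewise strict: a score exactly at the threshold
is Low.

Arm-level changes are called when gain- (or loss-) called segments cover
at least half of an arm's unmasked bins (`min_arm_fraction = 0.5`); a
bin belongs to the arm containing its midpoint, so bins straddling the
centromere go to the arm holding more than half of the bin.

## Cohort statistics

All statistics are exported individually and mirror the conventions of
the standard desktop statistics packages they are checked against:

* `fisher_exact_two_sided`: two-sided p by point-probability summation
  over margin-fixed tables (verified against an exhaustive enumeration
  oracle for every 2×2 table with total ≤ 30).
* `cramers_v`: `sqrt(chi2 / (n (min(r,c) − 1)))` with the *uncorrected*
  Pearson chi-square — a continuity correction would not reproduce the
  conventional values on 2×2 tables.
* `independent_t_test`: Student's pooled-variance t by default, Welch by
  flag.
* `logistic_univariate`: IRLS maximum likelihood with Wald confidence
  intervals; the predictor can be log10-transformed and standardized
  first (the transform used for CIN scores, whose distribution is
  right-skewed). Complete and quasi-complete separation — a predictor
  that perfectly orders the outcome classes — is detected by the
  order-statistics check and reported as a flag instead of a divergent
  odds ratio, which would otherwise be solver-noise.
* `roc_auc` / `youden_threshold`: empirical ROC over all thresholds;
  AUC equals the Mann-Whitney U statistic with half credit for ties
  (asserted against a pairwise-comparison oracle); the 95% CI uses the
  Hanley–McNeil standard error (DeLong-style resampling is deliberately
  out of scope); the Youden threshold maximizes sensitivity +
  specificity − 1 with ties broken toward higher specificity.

### The packaged patient cohort

`load_breast_cohort()` ships 29 patient records (age, tumor size,
histology, ER/PR/HER2, Ki67, molecular subtype, SLNB outcome, CIN
group). Its per-patient `arm_changes` column is a *reconstruction*: the
source records constrain only the pairwise cross-tabulations of arm
changes against CIN group and against SLNM, and the packaged assignment
(10 of the 16 CIN-High patients, 3 of the 8 CIN-Low SLNM-positive
patients, lowest sample IDs in each stratum) reproduces both exactly.
Every statistic the package computes from the column depends only on
those margins, so the arbitrary choice within the consistent set is
immaterial; analyses that would depend on the joint assignment should
not use this column. The cohort's continuous CIN scores are not part of
the record (only High/Low labels are), so absolute-score statistics —
group score means, their t-test, the score-based AUC and odds ratio, and
the absolute cutoff — cannot be recomputed from the packaged data and
are not acceptance surfaces; the simulation-based analyses below stand
in for them as property checks.

## The synthetic-data generator

`sim_config`/`simulate_cohort` emulate the study design: a diploid
control panel, 24 metastatic-like and 5 non-metastatic-like tumors, and
an aberration catalog of single-copy arm events — gains on 1q and 8q,
losses on 12q, 16q, 17p, 17q — included per tumor with probability 0.6
(metastatic-like) vs 0.1 (non-metastatic-like). Counts are negative
binomial; a segment at integer copy number c in a tumor of purity p has
mean `depth × (2(1−p) + pc)/2`. Purity is uniform on (0.6, 0.9) and the
default depth, 645 fragments per bin, is the 10-million-read-pair preset
on the default 200-kb hg19 grid.

Defaults the data do not dictate, chosen once:

* **Dispersion** (NB size = 150, per-bin CV ≈ 9% at the default depth).
  FFPE-derived shallow WGS is overdispersed relative to Poisson, and 9%
  is in the range well-behaved 200-kb bin counts show after QC. The
  choice also respects an internal consistency requirement of the
  scoring model: with the gain/loss cut fixed at |Z| = 3, a single-copy
  event at purity p shifts a bin by `0.5 p / CV` standard deviations, so
  any CV above ~17% would make such events uncallable at *any* depth.
  A noise level at which the method's own detection rule cannot work
  would not emulate the data the method is meant for.
* **Arm-level events only** in the default catalog; focal events can be
  injected through explicit per-bin copy-number edits of the truth.
* **No GC bias, no subclonality, no read-level simulation.** Passing
  tests on this generator therefore demonstrate correctness of the
  normalization–segmentation–scoring chain under the model's own
  assumptions, not robustness to the technical artifacts of real
  libraries (GC waves, mappability dropouts, FFPE sequence damage).

## Problem sizes in the shipped analyses

The `analysis/` scripts and the acceptance script run the generator on
an hg19 grid at 2-Mb bins (~1,530 bins) with depth 500 and 500
permutations per split test — sizes at which the full 29-sample cohort
segments in a few seconds while every detection margin (bin Z shift vs
the ±3 cut) is the same as at 200 kb. The 200-kb default grid (~15,500
bins) remains the generator's default configuration and is exercised
directly by `make_bins` tests. Breakpoint-recovery checks use two-step
signals of 60 bins (steps of 5 SD) with 2,000 permutations, and the
oracle-equivalence checks cover vectors up to length 50, where
exhaustive search is exact.

## Known limitations

* Absolute CIN scores are configuration-relative; cross-study score
  comparisons require identical bin width, panel and length unit.
* The permutation test assumes exchangeable bins within a chromosome
  under the null; long-range coverage waves would inflate split calls.
* Arm calls use a hard 50% coverage rule and do not model focal events
  spanning the centromere.
* The QC stage performs whole-pair rejection only (no adapter trimming)
  and reports the alignment-based error rate as unavailable, since the
  pipeline ingests coverage rather than alignments.
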