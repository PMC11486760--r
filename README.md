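# cinscore

Chromosomal instability (CIN) — frequent chromosome- and arm-level
copy-number gains and losses — marks aggressive breast tumors, and a
genome-wide CIN burden measured before surgery can help predict whether
the sentinel lymph node already carries metastasis (SLNM). `cinscore`
implements a complete CIN quantification pipeline for low-pass
whole-genome sequencing (~0.1–1× depth, where binned fragment counts
proxy copy number, not base-level variants), together with the
cohort-level statistics that relate CIN status to SLNM. It is aimed at
computational biologists analyzing shallow-WGS tumor cohorts and at
anyone who wants the scoring method as reusable, tested components.

## Method

For a genome tiled into fixed-width bins (200 kb by default), a tumor's
raw per-bin coverage is standardized against a panel of m diploid
controls:

    Z_bin = (coverage_raw − mean(coverage_controls)) / sd(coverage_controls)

with the sample (m−1) standard deviation; zero-variance bins are masked.
Circular binary segmentation (CBS) then partitions each chromosome's Z
vector: the arc/complement split maximizing the absolute pooled-variance
t-statistic is accepted when a seeded permutation test gives
p = (1 + k)/(1 + N) < α (default α = 0.01, N = 10,000), recursing on the
pieces. Segments with mean Z above +3 are gains, below −3 losses, and
the genome-wide score is

    CIN score = Σ over aberrant segments of L_seg × |Z_seg|

with L in bins by default. A cohort-derived cutoff (Youden-optimal on
the ROC against the outcome) splits samples into CIN-High/CIN-Low, and
arm gains/losses are called when aberrant segments cover ≥ 50% of an
arm. The statistics layer provides two-sided Fisher exact tests
(point-probability summation), Cramér's V from the uncorrected
chi-square, Student's t, univariate logistic regression on
log10-standardized scores with separation detection, and ROC/AUC
(Mann–Whitney with Hanley–McNeil CI). A negative-binomial simulator
generates control panels and two-group tumor cohorts with known truth
(arm-level events at configurable inclusion probabilities and purity),
so the whole chain is testable without any sequencing data.

## Worked example

The packaged 29-patient breast-cancer cohort (clinical covariates, SLNB
outcome, CIN group):

```r
library(cinscore)
stats <- cohort_association_stats(load_breast_cohort())
subset(stats$by_slnm, variable %in% c("cin_group", "arm_changes"))
#>       variable      p     v
#> 9  arm_changes 0.0476 0.411
#> 10   cin_group 0.0108 0.506
round(stats$classification, 3)
#> sensitivity specificity
#>       0.667       1.000
```

CIN-High associates with SLNM (Fisher p = 0.011, Cramér's V = 0.506,
a moderately strong association); as a preoperative predictor it has
sensitivity 0.67 and specificity 1.00 in this cohort. Arm-level changes
associate more weakly (p = 0.048, V = 0.411).

A simulated cohort through the full pipeline — 24 metastatic-like vs 5
non-metastatic-like tumors (arm-event probabilities 0.6 vs 0.1, purity
0.6–0.9) on an hg19 grid at 2-Mb bins:

```r
cfg <- sim_config(genome = hg19_genome(), bin_width = 2e6, depth = 500,
                  n_controls = 20, seed = 1)
coh <- simulate_cohort(cfg)
res <- run_cohort(coh, cbs_params(n_permutations = 500, rng_seed = 1))
head(res$scores, 3)
#>     sample      group cin_score has_arm_changes cin_group
#> 1 tumor_01 metastatic     599.7            TRUE      High
#> 2 tumor_02 metastatic     904.4            TRUE      High
#> 3 tumor_03 metastatic     581.1            TRUE      High
```

Here `cin_score` is in bin × |Z| units on the 2-Mb grid (absolute scores
are configuration-relative), and `cin_group` is the label at the
cohort's own Youden threshold. For this seed the run prints AUC 0.992,
a Youden threshold of 186.5 with sensitivity 0.958 and specificity
1.000, and High/Low × group Fisher p = 5.1e-05 (V = 0.894) — the
metastatic-like group separates cleanly, as the generator intends.

The numbered scripts under `analysis/` run these analyses end to end
(cohort tables → simulation → segmentation and scoring → group
statistics) and write their tables under `results/`.

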