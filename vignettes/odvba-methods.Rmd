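---
title: "Optimally-discriminative voxel-based analysis: models, parameters and design choices"
author: "odvba package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimally-discriminative voxel-based analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odvba)
```

## The problem

Voxel-based morphometry (VBM) compares tissue-density maps — here
mass-preserving RAVENS-style gray/white-matter density volumes registered to
a common template — between two groups, voxel by voxel. The conventional
pipeline smooths every subject's map with a fixed isotropic Gaussian kernel
and then runs a voxelwise two-sample test. A fixed kernel is a blunt
instrument: it blurs sharp-edged group differences into their surroundings
(losing specificity) and dilutes weak extended differences (losing
sensitivity).

Optimally-discriminative voxel-based analysis (ODVBA) replaces the fixed
kernel with a locally learned, anisotropic, non-negative filter. The brain
is decomposed into many small overlapping neighborhoods; in each one a
non-negative weight vector is learned that best discriminates the two
groups; and every voxel's final statistic tallies its learned weights,
multiplied by the neighborhood-level group statistic, across all the
neighborhoods that contain it. Significance is assessed nonparametrically by
permuting group labels, with cluster-wise family-wise-error (FWE) correction
computed from the permutation distribution of the maximum cluster size.

This package implements that whole pipeline — synthetic cohort generation
with known ground truth, nuisance-covariate removal, the neighborhood
discriminative analysis, permutation inference, and atlas-partitioned
reporting — so every stage can be validated end to end without access to any
restricted clinical data.

## The discriminative neighborhood model

For one neighborhood with $m$ member voxels, let $X$ be the $n \times m$
matrix of the $n$ subjects' densities at those voxels, split into groups $A$
(the group of interest) and $B$. With class mean vectors $\mu_A, \mu_B$ the
scatter pair is

$$S_b = (\mu_A - \mu_B)(\mu_A - \mu_B)^\top, \qquad
  S_w = \frac{1}{n-2}\sum_{c \in \{A,B\}} \sum_{i \in c}
        (x_i - \mu_c)(x_i - \mu_c)^\top,$$

and the learned filter is

$$w^\star = \arg\max_{w \ge 0,\ \|w\|_2 = 1} \; w^\top (S_b - \lambda S_w)\, w .$$

This is a Fisher-style trade-off: reward projecting onto the group-mean
difference, penalize within-group variance, and constrain the filter to be
non-negative so it acts as an (anisotropic) local averaging kernel rather
than an arbitrary contrast. The neighborhood statistic $s$ is the
pooled-variance two-sample $t$ of the projections $Xw^\star$, signed so that
a deficit in the group of interest is positive under the `"less"` direction.
The whole-brain map is the tally

$$\phi_i = \sum_{k\,:\, i \in \mathcal{N}_k} w_{k,i}\, s_k .$$

Because each one-sided hypothesis has its own sign convention, two-direction
studies run the pipeline twice (`direction = "less"` and `"greater"`), as
`run_config()` does when both comparisons are requested.

### The trade-off weight λ

The criterion's only free weight defaults to the scale-free per-neighborhood
heuristic $\lambda = \operatorname{tr}(S_b)/\operatorname{tr}(S_w)$, which
balances the two terms regardless of the local density scale. A fixed
numeric `lambda` can be supplied instead through [odvba_params()]. With
$\lambda = 0$ the solution concentrates on the largest mean difference;
very large $\lambda$ forces the filter into the lowest-variance direction.

### Solving under the non-negativity constraint

The objective is an indefinite quadratic over the non-negative unit sphere —
non-convex, so the solver contract matters. `solve_ndp()` runs projected
gradient ascent (clip negatives to zero, renormalize) with a backtracking
line search, which makes the accepted objective sequence non-decreasing.
Because projected ascent from a single start can stall in a local optimum of
an indefinite quadratic, the solver is run from a small deterministic set of
feasible starts — the uniform vector, the clipped $\pm(\mu_A - \mu_B)$
directions, and the dominant diagonal axis — and the best stationary point
wins; the best single-coordinate solution $\max_i A_{ii}$ is always a
candidate, which also covers collapse of the iterate to the zero vector.
On small instances the result is verified in the test suite against a
dense-grid brute-force search over the positive orthant of the unit sphere
(`ndp_grid_oracle()`): across 100 random scatter instances of dimension 2-4
the solver's objective must be within $10^{-3}$ of the grid optimum.

Degenerate inputs have fixed conventions: identical class means ($S_b = 0$)
skip the solve and contribute $s = 0$ with a uniform $w$; a zero pooled
variance of the projections also yields $s = 0$ (flagged as degenerate)
rather than an infinite $t$.

### Neighborhood geometry

Neighborhoods are Euclidean balls in millimetres (`radius_mm`, default 2 mm)
centred on a stride-subsampled lattice of in-mask voxels (`stride`, default
1: every in-mask voxel is a centre). Neighborhoods with fewer than two
in-mask members are dropped, and construction fails loudly ("coverage
error") if any in-mask voxel then belongs to no neighborhood — the tally is
only meaningful when every voxel is covered. The defaults give 33-member
interior neighborhoods on a 1 mm grid, small enough that the per-neighborhood
$m \times m$ eigenproblem stays cheap and the learned filters stay local.

## Permutation inference

Under the null hypothesis of no group difference, group labels are
exchangeable. `permutation_pvalues()` re-randomizes labels (preserving group
sizes) and recomputes the *entire* map — the discriminative weights are
re-learned for every permutation (`relearn = TRUE`). Freezing the observed
weights and only re-scoring projections would break exchangeability, because
the weights were themselves chosen to separate the observed labeling; the
frozen mode exists (`relearn = FALSE`) for quick smoke runs and is labelled
approximate.

Voxel p-values use the add-one estimator
$p_i = (1 + \#\{\phi^*_i \ge \phi_i\})/(n_{\text{perm}} + 1)$, which never
returns zero and gives the exact achievable floor $1/(n_{\text{perm}}+1)$;
ties count toward the null (conservative). With
`permutation_scheme(exhaustive = TRUE)` all distinct labelings are
enumerated instead, and the estimator reduces exactly to the exhaustive
permutation p — the test suite verifies this equality on a 2-vs-2 cohort
against direct enumeration.

For cluster-wise FWE correction, each permutation's own map is thresholded
at the cluster-forming level (uncorrected $p < 0.05$ by default, the same
threshold used for display of trends) and the maximum cluster size is
recorded; an observed cluster of size $N$ then gets
$p_{\text{FWE}} = (1 + \#\{\text{null max} \ge N\})/(n_{\text{perm}}+1)$,
which is monotone in $N$. Connectivity defaults to 26 (vertex-touching
voxels connected), the common volumetric convention; 6 and 18 are available
and covered by fixture tests. The cluster-forming threshold and the
connectivity are declared defaults of this implementation, not values
inherited from any particular study.

One discreteness note: with $n_{\text{perm}} = 99$ the achievable p-values
are $k/100$, so the event $p < 0.05$ has exact probability $0.04$ under the
null — slightly conservative, which is the expected behaviour of the add-one
estimator at small $n_{\text{perm}}$.

## Nuisance-covariate removal

Preprocessing ends with voxelwise multiple linear regression of each
density value on intracranial volume, age, clinic site (reference-coded
indicators) and time from randomization to scan. Continuous covariates are
mean-centred, so the fitted intercept is the prediction at the covariate
means; `residualize()` returns residual + intercept, keeping adjusted maps
on the density scale (the region-level $t$ statistics downstream are
computed on mean densities, which should remain interpretable).

The model is fit pooling both arms *without* a group term: in a randomized
design, assignment is independent of the covariates in expectation, so the
nuisance fit cannot systematically absorb the group effect — a property the
test suite checks on synthetic cohorts (the planted group difference is
unchanged by residualization within sampling error). For non-randomized
applications a protected group indicator can be added
(`build_design(..., protect_group = TRUE)`); the protected column is never
subtracted.

Adjusted values are deliberately *not* clipped at zero by default: clipping
would destroy the exact orthogonality of residuals to the design (which the
tests assert at $10^{-10}$) for a cosmetic gain. `clip = TRUE` restores hard
non-negativity when adjusted maps are exported as images.

Between-site dispersion is quantified by `site_dispersion()`: the sample
mean of whole-volume density per site, then IQR, mean absolute deviation
about the mean, range and sample SD across the site means. MAD here is the
*mean* absolute deviation (not the median-based estimator), and the IQR
uses linear-interpolation quantiles; both conventions are fixed so the
numbers are reproducible.

## Baseline-balance statistics

`chi_square_homogeneity()` computes the Pearson chi-square test of
homogeneity — no continuity correction — on category-by-arm count tables,
reporting p in percent, the convention of baseline-characteristics tables
in randomized trials. `characteristics_report()` assembles the table with
per-variable complete-case denominators (missing values are excluded
variable by variable, so denominators may differ across variables).
Single-category variables have no test (df = 0) and report NA. The
package's regression tests pin the computed p-percent values for a set of
published multi-category count rows, stored as a plain-CSV input under
`inst/extdata/`.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture: it defines
the study conditions under which every downstream claim is validated. Each
subject's volume is

> baseline field + Σ (covariate slope × covariate) + site offset +
> spatially correlated noise − planted deficit (treated arm only),
> clipped at zero.

* **Baseline**: a constant (0.5) plus low-frequency cosine components —
  smooth, brain-like spatial heterogeneity without shipping a template.
* **Noise**: white Gaussian noise convolved with a Gaussian kernel
  (`smoothness_fwhm`, default 3 mm), rescaled so the marginal SD equals
  `noise_sigma` — emulating the smooth residual structure of registered
  tissue maps.
* **Covariates**: age uniform 65-80 y; ICV normal, mean 1400 mL, 10% CV;
  clinic site uniform over `n_sites` (default 4) with fixed density
  offsets; time-to-scan uniform 1.4-3.0 y, spanning the recruitment lags of
  the two-arm design it emulates; binary sensitivity flags (low baseline
  cognition, diabetes) at 7% each.
* **Planted effect**: a sharp-edged ellipsoidal density reduction
  (`effect_size`, default 0.1 against `noise_sigma` 0.1 — an effect size
  near 1) in the anterior part of the mask.
* **Scale**: densities are unit-scale (baseline about 0.5), and clipping at
  zero (rather than a logit transform) enforces non-negativity — the
  simplest invariant-preserving choice, with negligible distortion at the
  default noise levels.

The default grid is a 24³ desk-scale volume with an ellipsoidal mask, so a
full 2,000-permutation run completes in minutes on one CPU. The generator is
a pure function of its config, including the seed; determinism is asserted
bit-for-bit in the tests.

What the generator does *not* emulate: raw T1 contrast, skull stripping,
segmentation or registration error (its volumes are already "perfectly
registered"), non-Gaussian artifact tails, spatially varying covariate
effects, or longitudinal correlation. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated under honest synthetic
conditions — they do not certify performance on any particular clinical
dataset.

The synthetic atlas (`generate_atlas()`) partitions the mask into connected
regions by seeded region growing (6-connected, ties to the lower label,
unreachable voxels to the nearest seed) and assigns left/right by the sign
of the world x coordinate of each region's centre of mass; the default grid
is centred, so x = 0 is the midline.

## Reporting

`make_report()` emits one row per atlas region containing significant
voxels, at the FWE-corrected and at the uncorrected (trend) level: region
name, side, centre of mass in mm, significant-voxel count N, and the
pooled-variance two-sample t of the per-subject mean adjusted density over
the region's detected voxels (all detected voxels of a region pooled, not
per cluster). Coordinates are reported in the working template's own mm
frame; no stereotaxic-space affine conversion is embedded. Significant
voxels falling outside every atlas region are reported as "unassigned",
never dropped, and the row N's sum to the total count by construction.
Region t values are computed on the adjusted (residualized) maps, the same
data the statistic map was built from.

## Validation problem sizes

The package's own calibration studies (mirrored in `tests/` and
`scripts/acceptance.R`) use desk-scale problems chosen so the full suite
runs in minutes while keeping every estimate's Monte-Carlo error well
inside its decision band: 100 null replicates on a 16³ grid (15 subjects
per arm, 99 permutations each, weights re-learned in every permutation) for
voxel-p and cluster-FWE calibration; a 24³ grid with 20 per arm and 199
permutations for the detection benchmark against the Gaussian-smoothed
voxelwise-t baseline (smoothing FWHM matched to the neighborhood diameter,
identical relabelings, identical thresholds); 60 subjects at noise 0.02 for
nuisance-parameter recovery; and 100 random scatter instances for the
solver-vs-brute-force check.

## Known limitations

* The per-neighborhood optimum is a stationary point of a non-convex
  problem; the multi-start scheme is validated against brute force on small
  neighborhoods, but global optimality in large neighborhoods is not
  guaranteed (nor required — the permutation test is valid for any
  label-equivariant statistic).
* Permutation inference with full re-learning is the dominant cost; it is
  embarrassingly parallel across permutations but implemented serially (the
  tally is an integer-count reduction, so a parallel implementation would
  be reduction-order independent).
* The nuisance model is a fixed-effects linear model; no site random
  effects or nonlinear age terms.
* Only two-group comparisons; no multi-class extension.
* `relearn = FALSE` is approximate and must not be used for reported
  p-values.
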