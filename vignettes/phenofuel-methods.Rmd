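---
title: "Phenological fuel mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenological fuel mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofuel)
```

## The problem

Conventional fuel maps describe the *structure* of vegetation (species,
height, load). phenofuel instead maps *functional* fuel classes from the
seasonal dynamics of coarse-resolution satellite greenness: places that
green up and dry out on similar schedules burn on similar schedules, even
when their structural composition differs. The pipeline takes a multi-year
stack of seasonal NDVI composites, summarizes each pixel's mean seasonal
cycle by three Fourier descriptors, partitions the landscape into
contiguous phenologically homogeneous units, groups those units into a
few phenological fuel classes (PFCs), and then quantifies how strongly
fire ignitions select for or against each class.

## The seasonal signal model

For a pixel whose season is sampled at `N` regular composites
(`N = 11` 16-day composites from Julian day 113 to 273 by default), the
mean profile `x_t`, `t = 0..N-1`, is decomposed as

* `A0 = (1/N) * sum(x_t)` — the additive term, the seasonal mean NDVI, a
  proxy for seasonal productivity (fuel amount);
* `A_k = sqrt(a_k^2 + b_k^2)` for `k = 1, 2`, with
  `a_k = (2/N) * sum(x_t * cos(2*pi*k*t/N))` and the analogous sine term —
  the amplitudes of the one-cycle and two-cycle harmonics, measuring
  seasonality (fuel flammability via the moist-to-dry transition).

Phases are discarded: two pixels with the same amplitude but shifted
timing land in the same class. The `2/N` normalization is a deliberate
convention — a unit-amplitude cosine yields `A1 = 1` exactly — chosen
because commercial implementations of the same decomposition do not
document their scaling; any fixed rescaling of the amplitude images
changes only the numeric meaning of the segmentation scale parameter, not
the ordering or topology of any downstream result.

Averaging over years precedes the decomposition. A pixel is kept only if
every composite index has at least `min_years_valid` unmasked years
(default `ceiling(n_years/2)`): a profile mixing different year subsets
across the season would confound seasonality with data availability.

## Segmentation into phenological units

The three amplitude bands are segmented by bottom-up pairwise region
merging in the fractal net evolution style. Each segment keeps running
sums, sums of squares, a 4-edge perimeter `l`, and a bounding box, so the
heterogeneity increase of a candidate merge is

```
dh_color = sum_b w_b * [ n_m sd_m,b - (n_1 sd_1,b + n_2 sd_2,b) ]
dh_shape = cw * (n l / sqrt(n))_change + (1 - cw) * (n l / b)_change
cost     = (1 - sw) * dh_color + sw * dh_shape     (clamped at 0)
```

with population standard deviations (variance clamped at zero against
rounding), `b` the bounding-box perimeter, `sw` the shape weight and `cw`
the compactness weight. A merge is accepted while `cost < scale^2`.

The treatment order is *local mutual best fitting with deterministic
ascending-id visits*: passes repeat over segments in ascending id order,
a segment merges with its minimum-cost neighbour only when the choice is
mutual, ties go to the lower id, and the surviving segment takes the
smaller id. This replaces the undocumented proprietary treatment order of
commercial implementations; bit-compatibility with them is explicitly not
a goal, reproducibility is. Nodata pixels are removed from the adjacency
graph, so units never bridge nodata gaps. A cleanup pass then absorbs any
unit below `min_pixels` into its most colour-similar edge-neighbour
(shape ignored, smallest unit first, ties to lower ids); the cleanup is a
fixed point on conforming inputs.

Default parameters are the reference parameterization for 250 m seasonal
amplitude images: `scale = 500`, `shape_weight = 0.2`,
`compactness_weight = 0.8`, `min_pixels = 25`, 4-connectivity. The scale
parameter is the only size control and was originally chosen by expert
trial and error; it is exposed as configuration precisely because that
choice is not reproducible from data. On small synthetic scenes,
appropriate scales are of order 1–10 (the threshold is `scale^2` on an
absolute heterogeneity increase, which grows with segment size and
contrast).

Two numerical notes. First, because the final cost is clamped at zero, a
strongly negative shape change (merging two fragments into a compact
whole) can offset a small colour contrast; with `shape_weight > 0` this
occasionally lets a merge cross a weak class boundary. Ground-truth
recovery tests therefore run with `shape_weight = 0`, where the class
map is a pure colour construct and recovery is exact over a wide scale
range. Second, merge costs are memoized per segment and invalidated when
a neighbourhood changes; this is purely an optimization and provably does
not alter the merge sequence.

## Clustering units into fuel classes

Units are clustered by UPGMA (unweighted average linkage) on Euclidean
distances over `(mean_A0, mean_A1, mean_A2)`. Features are *not*
standardized by default: the three descriptors share NDVI units, and
rescaling would change the relative influence of productivity versus
seasonality; `standardize = TRUE` is available where the A0 range
dominates. The dendrogram is cut into `k` classes (here `k` is a user
choice, typically 3; automatic selection is out of scope) and classes are
labelled `PFC1..PFCk` by decreasing mean seasonal amplitude, so PFC1 is
always the most seasonal — and empirically the most fire-prone — class.

The published analysis additionally divided its largest class in two on
expert geographic knowledge (coastal versus inland). That criterion is
not algorithmically specified anywhere, so the package provides a clearly
labelled *surrogate*: 2-means on unit centroids (50 restarts, fixed
seed), with subgroup `a` the one nearer on average to the convex hull of
the unit centroids (a coastal-proximity proxy). It reproduces the spirit
— a spatial split of a phenologically broad class — but must not be
presented as the original expert split.

## Fire selectivity

For zones (units or classes) with fire counts `n_c`, total `N`, areas
`a_c`, total `A`, the selection ratio is `sigma_c = (n_c/N) / (a_c/A)`;
1 is the random-ignition expectation and the area-weighted mean of
`sigma` is identically 1. Three tests accompany it:

* **Multinomial Monte Carlo.** Fires are reallocated to zones with
  area-proportional probabilities; two-tailed p-values use the doubled
  smaller tail with add-one continuity,
  `p = min(1, 2*min(#le+1, #ge+1)/(reps+1))`. The published description
  ("as low or lower / as high or higher") does not fix how the two tails
  combine; the doubled-tail rule was chosen for symmetry and internal
  consistency, and single-tail reporting is available via `tail=`.
* **Permutational one-way ANOVA** on per-unit `sigma` across classes:
  classical F, p by uniform label permutation (one-tailed in large F,
  add-one rule). Units are unweighted — no area weighting is applied, as
  none is described for the original analysis. If the within-group sum
  of squares is zero, F is reported as infinite and p as its minimum
  attainable value.
* **A-posteriori pairwise F tests**, one per unordered class pair,
  unadjusted for multiplicity (matching the original presentation). Each
  pair consumes an independent seed derived from the master seed; whether
  the original analysis reused one permutation stream per pair is
  unknowable, and the choice does not affect any single pair's test.

Fires outside the grid or on nodata are excluded with a logged count
rather than an error, mirroring the exclusion of non-combustible classes
upstream.

## Environmental association

Fires are cross-classified by PFC against a categorical covariate
(land-cover macro-class, climatic region). The observed Pearson
chi-square is compared with randomizations that permute the covariate
label *vector* across fires — the exact construction described for the
original analysis, which automatically fixes both margins. Cell-level
two-tailed p-values use the same doubled-tail add-one rule as the Monte
Carlo test; a cell's direction is `+` when its observed count exceeds its
permutation-null mean. Cell-level significance of the published tables
cannot be reproduced exactly from print (the per-fire label vectors are
not recoverable from an aggregated table), which is why verification
against print is limited to the chi-square statistics and margins.

## The synthetic-scene generator

Every stage is tested against scenes with known truth. A scene is a set
of classes laid out as vertical strips or contiguous nearest-seed
patches; each class signal is
`base + amp1*cos(2*pi*t/N - phase1) + amp2*cos(4*pi*t/N - phase2)`,
i.e. cosines at exactly the first two discrete Fourier frequencies, so
`(base, amp1, amp2)` are the exact truths for `(A0, A1, A2)` at zero
noise. Per-year additive shifts model inter-annual variability and are
absorbed into A0 by the multi-year mean; observation noise is iid
Gaussian; all draws are clipped to `[-1, 1]`. Fires pick a pixel with
probability proportional to its class's `fire_multiplier` and land
uniformly within it, so the implied true selection ratio is
`m_c / sum_k (a_k/A) m_k`, with area-weighted mean 1 by construction.
Landscape and fires use independent seeds so fire statistics can be
replicated over a fixed landscape.

Default generator conditions mirror the study design the package targets:
13 years of 11 composites on a 250 m grid, observation noise
`sd = 0.02` and year effects `sd = 0.01` (a few percent of the NDVI
dynamic range, consistent with composited vegetation-index products),
four classes whose `(A0, A1, A2)` follow the empirical gradient of
decreasing productivity with increasing seasonality toward fire-prone
classes. What the generator does *not* emulate: spatially correlated
noise, cloud/quality dropouts, mixed pixels at class boundaries,
within-class gradients, or point-process clustering of ignitions. Tests
passing on these scenes validate the estimators' arithmetic and
calibration, not their robustness to those real-data pathologies.

## Problem sizes and tolerances in the test-suite

Ground-truth recovery runs on 40x40 to 100x100 scenes (a 100x100
four-class scene segments in well under a second); calibration checks
use 120–500 replicates with 99–999 randomizations each, sizes at which
the binomial/KS tolerances used (3 standard errors; KS p > 0.01) are
meaningful without being fragile. Published-table checks are exact to
print precision (2 decimals for selection ratios, 0.5 absolute on
chi-square statistics in the 8000–9500 range). Amplitude recovery on
pure cosines is asserted to 1e-12; running-sum statistics against
brute-force recomputation to 1e-9.

## Known limitations

* The 60 published Sardinian phenological units, the global F = 30.56,
  and the pairwise F table depend on the original MODIS imagery and
  per-unit selection ratios, which are not published; they are verified
  here only through property-based substitutes on synthetic scenes.
* Rasters are exchanged as plain-text ESRI ASCII grids and all layers
  must already share one projected frame; there is no CRS handling or
  reprojection, by design.
* Harmonics above order 2, gap filling, phase maps, hierarchical
  multi-level segmentation, and automatic selection of `k` are out of
  scope.

## A worked miniature

```{r example, eval = FALSE}
specs <- list(
  pheno_class_spec(1, 0.30, 0.20, 0.08, fire_multiplier = 3),
  pheno_class_spec(2, 0.45, 0.14, 0.05, fire_multiplier = 1.5),
  pheno_class_spec(3, 0.60, 0.08, 0.03, fire_multiplier = 0.8),
  pheno_class_spec(4, 0.75, 0.04, 0.01, fire_multiplier = 0.3))
cfg <- scene_config(60, 60, specs, n_years = 5, noise_sd = 0.01,
                    n_fires = 5000, layout = "blocks")
cm  <- generate_class_map(cfg)
run <- run_phenofuel(generate_ndvi_stack(cm, cfg),
                     generate_ignitions(cm, cfg),
                     params = seg_params(scale = 2, shape_weight = 0,
                                         min_pixels = 25),
                     k = 4, split_largest = FALSE,
                     n_reps = 999, seed = 1)
print(run)
true_selection_ratios(cm, cfg)
```
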