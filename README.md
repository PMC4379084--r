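# phenofuel

Phenological fuel mapping from seasonal NDVI time-series, with fire
selectivity statistics.

Wildfire fuel maps usually describe vegetation *structure*. phenofuel
builds *functional* fuel classes instead: it classifies a landscape by
the seasonal timing of its greenness as seen by coarse-resolution
satellite sensors, and then measures how strongly fire ignitions select
for or against each class. It is aimed at fire ecologists and
remote-sensing analysts who have a stack of seasonal NDVI composites, a
fire-ignition point record, and categorical environmental layers, and
who want a reproducible, fully scripted version of this analysis chain —
plus a synthetic-scene generator that makes every stage testable against
known ground truth.

## The method

1. **Temporal Fourier analysis.** Each pixel's multi-year mean seasonal
   NDVI profile x_t (t = 0..N−1, default N = 11 16-day composites) is
   summarized by the additive term A0 = (1/N)Σx_t (seasonal
   productivity) and the first two harmonic amplitudes
   A_k = √(a_k² + b_k²), a_k = (2/N)Σx_t·cos(2πkt/N),
   b_k = (2/N)Σx_t·sin(2πkt/N), k = 1, 2 (seasonality). Phases are
   discarded.
2. **Segmentation.** The (A0, A1, A2) image is partitioned into
   contiguous phenological units (PUs) by bottom-up pairwise region
   merging (fractal net evolution): merges minimize the increase in
   weighted colour + shape heterogeneity and are accepted while that
   increase stays below scale²; undersized units are absorbed into their
   most similar neighbour (defaults: scale 500, shape 0.2, compactness
   0.8, minimum 25 pixels).
3. **Clustering.** Units are grouped into phenological fuel classes
   (PFCs) by UPGMA on Euclidean distances over their mean Fourier
   components, cutting the dendrogram at k classes ordered by decreasing
   seasonality; the largest class can be split in two spatial subgroups.
4. **Fire selectivity.** For each zone, the selection ratio
   σ_c = (n_c/N)/(a_c/A) compares its share of ignitions with its share
   of area (σ = 1 ⇔ random ignition). Significance comes from a
   multinomial Monte Carlo null (9999 randomizations by default),
   between-class differences from a permutational one-way ANOVA on
   per-unit σ with a-posteriori pairwise F tests, and associations with
   land cover / climate from Pearson χ² with margin-fixed randomization.

## A worked example

A synthetic four-class scene whose classes have known Fourier truth and
known fire selectivity; the run segments it, clusters the units, and
tests selectivity:

```r
library(phenofuel)
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
                     k = 4, split_largest = FALSE, n_reps = 999, seed = 1)
print(run)
#> Phenological fuel-mapping run
#>   4 unit(s) -> 4 class(es); 5000 fire(s) (0 excluded)
#> Monte Carlo fire-selectivity test (999 randomizations, two-tailed)
#>  zone n_fires  area sigma p_value
#>  PFC1    2650 56.25 2.120   0.002
#>  PFC2    1372 56.25 1.098   0.002
#>  PFC3     711 56.25 0.569   0.002
#>  PFC4     267 56.25 0.214   0.002
round(true_selection_ratios(cm, cfg), 3)
#>     1     2     3     4
#> 2.143 1.071 0.571 0.214
```

The four generator blocks are recovered exactly as four units; the
estimated selection ratios (2.12, 1.10, 0.57, 0.21) match the designed
truths within sampling error of 5000 fires, and every class departs
significantly from the random-ignition null (p = 0.002, the smallest
two-tailed value attainable with 999 randomizations).

`exec/phenofuel` exposes the same stages as a command line
(`simulate`, `fourier`, `segment`, `cluster`, `selectivity`,
`associate`, `run-all`), and `vignettes/phenofuel-methods.Rmd` documents
the models, parameter meanings, and design choices.

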