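Package: phenofuel
Title: Phenological Fuel Mapping from Seasonal NDVI Time-Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives phenological fuel maps from multi-year seasonal NDVI
    raster time-series and quantifies the fire-proneness of the resulting
    classes. The pipeline decomposes per-pixel mean seasonal NDVI profiles
    into a Fourier additive term and the first two harmonic amplitudes
    (A0, A1, A2), partitions the amplitude feature space into contiguous
    phenological units by bottom-up region merging (Fractal Net Evolution),
    clusters units into phenological fuel classes by UPGMA on unit-mean
    Fourier components, and tests class-level fire selectivity with
    selection ratios, multinomial Monte Carlo nulls, permutational ANOVA,
    and margin-fixed contingency-table randomization. A synthetic-scene
    generator with known phenological classes and known fire selectivity
    provides a ground-truth harness for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
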