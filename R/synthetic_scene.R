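# Synthetic scenes with known phenology and known fire selectivity.
#
# Each phenological class is a two-harmonic cosine signal on the seasonal
# composite grid, so the temporal Fourier step recovers the class parameters
# exactly at zero noise and every downstream stage can be checked against
# ground truth. Fires are placed with per-class intensity multipliers whose
# implied selection ratios are known in closed form.

#' Describe one synthetic phenological class
#'
#' The seasonal signal of a class is
#' `base_level + amp1*cos(2*pi*t/N - phase1) + amp2*cos(4*pi*t/N - phase2)`
#' at composite index `t = 0..N-1`, i.e. cosines at exactly the first two
#' discrete Fourier frequencies of the N-sample season. `base_level`, `amp1`
#' and `amp2` are therefore the exact truths for the additive term A0 and
#' the harmonic amplitudes A1, A2.
#'
#' @param class_id positive integer label.
#' @param base_level mean NDVI of the class, in `[0, 1]`.
#' @param amp1,amp2 amplitudes (NDVI units) of the 1-cycle and 2-cycle
#'   harmonics; nonnegative, and `base_level + amp1 + amp2` must stay in
#'   `[-1, 1]`.
#' @param phase1,phase2 phases in radians (discarded by the Fourier stage,
#'   which keeps amplitudes only).
#' @param fire_multiplier relative ignition intensity of the class
#'   (dimensionless, >= 0); the implied true selection ratio is
#'   `sigma_c = m_c / sum_k (a_k/A) m_k`.
#' @param covariate_label integer category written to the covariate map for
#'   pixels of this class (defaults to `class_id`).
#' @return list of class `pheno_class_spec`.
#' @export
pheno_class_spec <- function(class_id, base_level, amp1 = 0, amp2 = 0,
                             phase1 = 0, phase2 = 0, fire_multiplier = 1,
                             covariate_label = class_id) {
  stopifnot(length(class_id) == 1L, class_id >= 1L,
            base_level >= 0, base_level <= 1,
            amp1 >= 0, amp2 >= 0, fire_multiplier >= 0)
  if (base_level + amp1 + amp2 > 1 || base_level - amp1 - amp2 < -1)
    stop("class ", class_id, ": base_level +/- (amp1+amp2) leaves [-1, 1]")
  structure(list(class_id = as.integer(class_id),
                 base_level = base_level, amp1 = amp1, amp2 = amp2,
                 phase1 = phase1, phase2 = phase2,
                 fire_multiplier = fire_multiplier,
                 covariate_label = as.integer(covariate_label)),
            class = "pheno_class_spec")
}

#' Configure a synthetic scene
#'
#' Defaults mirror the study design the generator emulates: 13 seasons of
#' 11 16-day composites (Julian day 113 to 273) on a 250 m grid.
#'
#' @param n_rows,n_cols grid dimensions in pixels.
#' @param class_specs list of [pheno_class_spec()].
#' @param n_years number of seasons (default 13).
#' @param n_composites composites per season (default 11; must be >= 5 so
#'   two harmonics are resolvable).
#' @param noise_sd per-observation NDVI noise s.d.
#' @param year_effect_sd s.d. of the per-year additive NDVI shift (absorbed
#'   into A0 by the multi-year mean; it models inter-annual variability).
#' @param layout `"blocks"` (vertical strips) or `"seeded"` (contiguous
#'   nearest-seed patches grown from random seed pixels).
#' @param patch_seed,fire_seed RNG seeds; the landscape and the fires use
#'   independent seeds so fire statistics can be replicated over a fixed
#'   landscape.
#' @param n_fires number of ignition points.
#' @param pixel_size cell side in map units (metres; default 250).
#' @param first_day,time_lag start day-of-year and composite interval.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(n_rows, n_cols, class_specs,
                         n_years = 13, n_composites = 11,
                         noise_sd = 0.02, year_effect_sd = 0.01,
                         layout = c("blocks", "seeded"),
                         patch_seed = 1L, fire_seed = 2L,
                         n_fires = 1000L, pixel_size = 250,
                         first_day = 113L, time_lag = 16L) {
  layout <- match.arg(layout)
  stopifnot(n_rows >= 1, n_cols >= 1, n_years >= 1, n_composites >= 5,
            noise_sd >= 0, year_effect_sd >= 0, pixel_size > 0)
  if (!length(class_specs)) stop("at least one class spec is required")
  if (inherits(class_specs, "pheno_class_spec")) class_specs <- list(class_specs)
  ids <- vapply(class_specs, `[[`, 1L, "class_id")
  if (anyDuplicated(ids)) stop("duplicate class_id in class_specs")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 class_specs = class_specs,
                 n_years = as.integer(n_years),
                 n_composites = as.integer(n_composites),
                 noise_sd = noise_sd, year_effect_sd = year_effect_sd,
                 layout = layout,
                 patch_seed = as.integer(patch_seed),
                 fire_seed = as.integer(fire_seed),
                 n_fires = as.integer(n_fires),
                 pixel_size = pixel_size,
                 first_day = as.integer(first_day),
                 time_lag = as.integer(time_lag)),
            class = "scene_config")
}

scene_ids <- function(config)
  vapply(config$class_specs, `[[`, 1L, "class_id")

#' Generate the class map of a synthetic scene
#'
#' `"blocks"` places the classes as equal-width vertical strips in spec
#' order; `"seeded"` draws one random seed pixel per class and assigns every
#' pixel to its nearest seed (ties to the lower class id), yielding
#' contiguous patches. Deterministic given `patch_seed`.
#'
#' @param config a [scene_config()].
#' @return integer [pheno_grid()] of class ids.
#' @export
generate_class_map <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  ids <- scene_ids(config)
  k <- length(ids)
  nr <- config$n_rows; nc <- config$n_cols
  if (config$layout == "blocks") {
    if (k > nc) stop("more classes (", k, ") than columns (", nc, ")")
    strip <- ceiling(seq_len(nc) * k / nc)   # near-equal vertical strips
    m <- matrix(ids[strip], nr, nc, byrow = TRUE)
  } else {
    set.seed(config$patch_seed)
    seed_px <- sample.int(nr * nc, k)
    sr <- (seed_px - 1L) %% nr + 1L
    sc <- (seed_px - 1L) %/% nr + 1L
    row <- rep(seq_len(nr), nc)
    col <- rep(seq_len(nc), each = nr)
    d2 <- vapply(seq_len(k),
                 function(i) (row - sr[i])^2 + (col - sc[i])^2,
                 numeric(nr * nc))
    m <- matrix(ids[max.col(-d2, ties.method = "first")], nr, nc)
  }
  present <- ids %in% m
  if (!all(present))
    stop("class ", paste(ids[!present], collapse = ", "),
         " received zero area; use fewer classes or a larger grid")
  storage.mode(m) <- "integer"
  pheno_grid(m, cellsize = config$pixel_size)
}

#' Generate the multi-year NDVI stack of a synthetic scene
#'
#' Per pixel of class c, year y and composite t:
#' `signal_c(t) + yearEffect_y + eps`, `eps ~ N(0, noise_sd)`, clipped to
#' `[-1, 1]`. Deterministic given `patch_seed`.
#'
#' @param class_map integer [pheno_grid()] from [generate_class_map()].
#' @param config a [scene_config()].
#' @return an `ndvi_stack`: numeric array `(year, composite, pixel)` with
#'   attributes `grid`, `years`, `composite_days`, `time_lag`.
#' @export
generate_ndvi_stack <- function(class_map, config) {
  stopifnot(inherits(config, "scene_config"), inherits(class_map, "pheno_grid"))
  ids <- scene_ids(config)
  if (!all(stats::na.omit(unique(as.vector(class_map))) %in% ids))
    stop("class map contains ids absent from class_specs")
  N <- config$n_composites; Y <- config$n_years
  npix <- length(class_map)
  t <- seq_len(N) - 1
  sig <- vapply(config$class_specs, function(s)
    s$base_level + s$amp1 * cos(2 * pi * t / N - s$phase1) +
      s$amp2 * cos(4 * pi * t / N - s$phase2),
    numeric(N))                               # N x k
  colnames(sig) <- as.character(ids)
  set.seed(config$patch_seed)
  year_eff <- if (config$year_effect_sd > 0)
    stats::rnorm(Y, 0, config$year_effect_sd) else numeric(Y)
  vals <- array(NA_real_, dim = c(Y, N, npix))
  cls <- as.character(as.vector(class_map))
  base <- sig[, cls, drop = FALSE]            # N x npix
  for (y in seq_len(Y)) {
    eps <- if (config$noise_sd > 0)
      stats::rnorm(N * npix, 0, config$noise_sd) else 0
    vals[y, , ] <- base + year_eff[y] + eps
  }
  vals[vals > 1] <- 1; vals[vals < -1] <- -1
  vals[, , is.na(as.vector(class_map))] <- NA_real_
  structure(vals,
            grid = grid_template(class_map),
            years = seq(2000, length.out = Y),
            composite_days = config$first_day +
              config$time_lag * (seq_len(N) - 1L),
            time_lag = config$time_lag,
            class = "ndvi_stack")
}

#' @export
print.ndvi_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ndvi_stack> %d year(s) x %d composite(s) x %d pixel(s)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  composite days: %s\n",
              paste(attr(x, "composite_days"), collapse = " ")))
  invisible(x)
}

#' Generate ignition points over a synthetic scene
#'
#' A pixel is drawn with probability proportional to its class's
#' `fire_multiplier`, then the point is placed uniformly inside the pixel.
#' Deterministic given `fire_seed`. With equal multipliers this is the
#' random-ignition null (true selection ratio 1 everywhere).
#'
#' @inheritParams generate_ndvi_stack
#' @return an `ignition_set` with an attribute `true_class` (the generating
#'   class of each point).
#' @export
generate_ignitions <- function(class_map, config) {
  stopifnot(inherits(config, "scene_config"))
  if (config$n_fires < 1L) stop("n_fires must be positive")
  mult <- vapply(config$class_specs, `[[`, 1, "fire_multiplier")
  names(mult) <- as.character(scene_ids(config))
  if (all(mult == 0)) stop("all fire multipliers are zero")
  w <- mult[as.character(as.vector(class_map))]
  w[is.na(w)] <- 0
  set.seed(config$fire_seed)
  px <- sample.int(length(w), config$n_fires, replace = TRUE, prob = w)
  row <- (px - 1L) %% nrow(class_map) + 1L
  col <- (px - 1L) %/% nrow(class_map) + 1L
  cs <- attr(class_map, "cellsize")
  x <- attr(class_map, "xll") + (col - 1L + stats::runif(config$n_fires)) * cs
  y <- attr(class_map, "yll") +
    (nrow(class_map) - row + stats::runif(config$n_fires)) * cs
  out <- ignition_set(x, y)
  attr(out, "true_class") <- as.vector(class_map)[px]
  out
}

#' Covariate map derived from the class map
#'
#' Each class writes its `covariate_label`; a fraction `label_noise` of
#' pixels is then relabeled uniformly at random among the declared labels,
#' so association tests retain a known direction while imperfect.
#'
#' @inheritParams generate_ndvi_stack
#' @param label_noise fraction in `[0, 1)` of pixels to scramble.
#' @param seed RNG seed for the scrambling.
#' @return integer [pheno_grid()] of covariate categories.
#' @export
generate_covariate_map <- function(class_map, config, label_noise = 0,
                                   seed = config$patch_seed + 1L) {
  stopifnot(label_noise >= 0, label_noise < 1)
  labs <- vapply(config$class_specs, `[[`, 1L, "covariate_label")
  names(labs) <- as.character(scene_ids(config))
  m <- matrix(labs[as.character(as.vector(class_map))],
              nrow(class_map), ncol(class_map))
  if (label_noise > 0) {
    set.seed(seed)
    flip <- which(stats::runif(length(m)) < label_noise & !is.na(m))
    m[flip] <- sample(unique(labs), length(flip), replace = TRUE)
  }
  storage.mode(m) <- "integer"
  pheno_grid(m, xll = attr(class_map, "xll"), yll = attr(class_map, "yll"),
             cellsize = attr(class_map, "cellsize"))
}

#' True selection ratios implied by a scene
#'
#' `sigma_c = m_c / sum_k (a_k/A) m_k` with `m` the fire multipliers and
#' `a_k` the class areas on the realized class map. The area-weighted mean
#' of the result is 1 by construction.
#'
#' @inheritParams generate_ndvi_stack
#' @return named numeric vector of true selection ratios per class id.
#' @export
true_selection_ratios <- function(class_map, config) {
  ids <- scene_ids(config)
  mult <- vapply(config$class_specs, `[[`, 1, "fire_multiplier")
  a <- tabulate(match(as.vector(class_map), ids), length(ids))
  rel <- a / sum(a)
  sig <- mult / sum(rel * mult)
  names(sig) <- as.character(ids)
  sig
}
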