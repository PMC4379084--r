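# Independent reference implementations used as oracles. These deliberately
# recompute everything from raw data (no running sums, no package internals)
# so they exercise a second route to the same quantities.

# --- standard synthetic scenes -------------------------------------------

four_class_specs <- function(mult = c(3, 1.5, 0.8, 0.3)) {
  list(pheno_class_spec(1, 0.30, 0.20, 0.08, fire_multiplier = mult[1],
                        covariate_label = 1L),
       pheno_class_spec(2, 0.45, 0.14, 0.05, fire_multiplier = mult[2],
                        covariate_label = 2L),
       pheno_class_spec(3, 0.60, 0.08, 0.03, fire_multiplier = mult[3],
                        covariate_label = 2L),
       pheno_class_spec(4, 0.75, 0.04, 0.01, fire_multiplier = mult[4],
                        covariate_label = 3L))
}

zero_noise_scene <- function(n_rows = 40, n_cols = 40, ...) {
  cfg <- scene_config(n_rows, n_cols, four_class_specs(), n_years = 3,
                      noise_sd = 0, year_effect_sd = 0, layout = "blocks",
                      n_fires = 500, ...)
  cm <- generate_class_map(cfg)
  list(config = cfg, class_map = cm,
       stack = generate_ndvi_stack(cm, cfg))
}

# --- Fourier oracle: amplitudes via stats::fft ---------------------------

tfa_fft_oracle <- function(x) {
  N <- length(x)
  sp <- stats::fft(x)
  c(A0 = Re(sp[1]) / N, A1 = Mod(sp[2]) * 2 / N, A2 = Mod(sp[3]) * 2 / N)
}

# --- mean profile oracle: explicit loops ---------------------------------

mean_profile_oracle <- function(stack, min_years_valid) {
  d <- dim(stack)
  out <- matrix(NA_real_, d[2], d[3])
  valid <- rep(TRUE, d[3])
  for (p in seq_len(d[3])) {
    for (t in seq_len(d[2])) {
      v <- stack[, t, p]
      v <- v[!is.na(v)]
      if (length(v) < min_years_valid) valid[p] <- FALSE
      if (length(v)) out[t, p] <- mean(v)
    }
  }
  out[, !valid] <- NA_real_
  list(values = out, valid = valid)
}

# --- FNEA oracle: mutual-best merging with stats recomputed from raw
#     pixel lists at every step --------------------------------------------

oracle_seg_stats <- function(px, vals, nr) {
  r <- (px - 1L) %% nr + 1L
  cc <- (px - 1L) %/% nr + 1L
  v <- vals[px, , drop = FALSE]
  key <- paste(r, cc)
  internal <- sum(paste(r + 1L, cc) %in% key) + sum(paste(r, cc + 1L) %in% key)
  list(px = px, n = length(px),
       mean = colMeans(v),
       sd = apply(v, 2, function(z) sqrt(mean(z^2) - mean(z)^2)),
       l = 4L * length(px) - 2L * internal,
       w = max(cc) - min(cc) + 1L, h = max(r) - min(r) + 1L)
}

oracle_shared_edges <- function(px1, px2, nr) {
  r1 <- (px1 - 1L) %% nr + 1L; c1 <- (px1 - 1L) %/% nr + 1L
  k2 <- paste((px2 - 1L) %% nr + 1L, (px2 - 1L) %/% nr + 1L)
  sum(paste(r1 + 1L, c1) %in% k2) + sum(paste(r1 - 1L, c1) %in% k2) +
    sum(paste(r1, c1 + 1L) %in% k2) + sum(paste(r1, c1 - 1L) %in% k2)
}

oracle_cost <- function(s1, s2, vals, nr, params) {
  nm <- s1$n + s2$n
  sm <- oracle_seg_stats(c(s1$px, s2$px), vals, nr)
  d_color <- sum(params$band_weights *
                 (nm * sm$sd - (s1$n * s1$sd + s2$n * s2$sd)))
  cmp <- function(s) sqrt(s$n) * s$l
  smo <- function(s) s$n * s$l / (2 * (s$w + s$h))
  d_shape <- params$compactness_weight * (cmp(sm) - cmp(s1) - cmp(s2)) +
    (1 - params$compactness_weight) * (smo(sm) - smo(s1) - smo(s2))
  max((1 - params$shape_weight) * d_color + params$shape_weight * d_shape, 0)
}

# Full merge simulation following the published rule: ascending-id visits,
# mutual minimum-cost partner, ties to the lower id, accept while
# cost < scale^2. Returns the partition as a label vector (NA = nodata).
fnea_oracle <- function(vals, nr, nc, params) {
  npix <- nr * nc
  valid <- stats::complete.cases(vals)
  segs <- list()
  for (p in which(valid)) segs[[as.character(p)]] <- p
  adjacent <- function(px1, px2) oracle_shared_edges(px1, px2, nr) > 0
  repeat {
    merged <- FALSE
    ids <- sort(as.integer(names(segs)))
    for (i in ids) {
      ki <- as.character(i)
      if (is.null(segs[[ki]])) next
      best <- function(id) {
        kid <- as.character(id)
        nb <- Filter(function(j)
          j != id && adjacent(segs[[kid]], segs[[as.character(j)]]),
          sort(as.integer(names(segs))))
        if (!length(nb)) return(NULL)
        cost <- vapply(nb, function(j)
          oracle_cost(oracle_seg_stats(segs[[kid]], vals, nr),
                      oracle_seg_stats(segs[[as.character(j)]], vals, nr),
                      vals, nr, params), numeric(1))
        list(id = nb[which.min(cost)], cost = min(cost))
      }
      bi <- best(i)
      if (is.null(bi) || bi$cost >= params$scale^2) next
      bj <- best(bi$id)
      if (is.null(bj) || bj$id != i) next
      keep <- min(i, bi$id); drop <- max(i, bi$id)
      segs[[as.character(keep)]] <- c(segs[[as.character(keep)]],
                                      segs[[as.character(drop)]])
      segs[[as.character(drop)]] <- NULL
      merged <- TRUE
    }
    if (!merged) break
  }
  lab <- rep(NA_integer_, npix)
  ids <- sort(as.integer(names(segs)))
  for (s in seq_along(ids)) lab[segs[[as.character(ids[s])]]] <- s
  lab
}

# --- UPGMA oracle: recursive average linkage over raw point distances ----

upgma_oracle_cophenetic <- function(X) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    bestd <- Inf; bi <- bj <- NA
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; bi <- i; bj <- j }
    }
    coph[clusters[[bi]], clusters[[bj]]] <- bestd
    coph[clusters[[bj]], clusters[[bi]]] <- bestd
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  coph
}

# --- partition agreement --------------------------------------------------

adjusted_rand <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  mclust::adjustedRandIndex(a[keep], b[keep])
}
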