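# Fire selectivity of zones (phenological units or fuel classes).
#
# The selection ratio of zone c is sigma_c = (n_c / N) / (a_c / A): the
# share of ignitions relative to the share of area. sigma = 1 is the
# random-ignition expectation; > 1 marks fire-prone zones, < 1
# fire-avoiding ones. Significance comes from a multinomial Monte Carlo
# null (fires reallocated with area-proportional probabilities); class
# differences in per-unit sigma are tested by one-way permutational ANOVA.

#' Count ignition points per zone
#'
#' Each point is mapped to a grid cell via half-open pixel intervals (see
#' [cell_from_xy()]); points outside the extent or on nodata cells are
#' excluded and reported in the `n_excluded` attribute.
#'
#' @param zones integer zone raster ([pheno_grid()], e.g. unit labels or a
#'   [pfc_raster()]).
#' @param fires an `ignition_set`.
#' @param levels optional vector of zone ids defining the output order
#'   (defaults to the sorted ids present in the raster); empty zones get
#'   count 0.
#' @return named integer vector of counts with attribute `n_excluded`.
#' @export
count_fires_per_zone <- function(zones, fires, levels = NULL) {
  stopifnot(inherits(zones, "pheno_grid"))
  rc <- cell_from_xy(zones, fires$x, fires$y)
  z <- rep(NA_integer_, nrow(rc))
  inside <- !is.na(rc$row)
  z[inside] <- unclass(zones)[cbind(rc$row[inside], rc$col[inside])]
  if (is.null(levels)) levels <- sort(unique(as.vector(zones)))
  counts <- tabulate(match(z, levels), length(levels))
  names(counts) <- as.character(levels)
  attr(counts, "n_excluded") <- sum(is.na(z))
  counts
}

#' Selection ratios of zones
#'
#' @param counts fire counts per zone (named or plain numeric vector).
#' @param areas zone areas, any common unit (only relative areas matter);
#'   all > 0.
#' @return data.frame `zone`, `n_fires`, `area`, `rel_area`, `rel_fires`,
#'   `sigma`. The area-weighted mean of `sigma` is 1 by construction.
#' @export
selection_ratios <- function(counts, areas) {
  if (length(counts) != length(areas)) stop("counts and areas differ in length")
  if (any(areas <= 0)) stop("all zone areas must be positive")
  N <- sum(counts)
  if (N <= 0) stop("no fires to analyse")
  A <- sum(areas)
  sigma <- (counts / N) / (areas / A)
  data.frame(zone = if (is.null(names(counts)))
               as.character(seq_along(counts)) else names(counts),
             n_fires = as.vector(counts), area = as.vector(areas),
             rel_area = as.vector(areas / A),
             rel_fires = as.vector(counts / N),
             sigma = as.vector(sigma))
}

perm_p_two_tailed <- function(null_le, null_ge, n_reps) {
  # doubled smaller tail with add-one continuity
  min(1, 2 * min(null_le + 1, null_ge + 1) / (n_reps + 1))
}

#' Monte Carlo test of zone-level fire selectivity
#'
#' Under the null, all N fires are reallocated to zones by a multinomial
#' draw with area-proportional probabilities; the observed selection
#' ratios are compared with `n_reps` such randomizations. Two-tailed
#' p-values use the doubled smaller tail with add-one continuity
#' (`tail = "low"`/`"high"` report a single tail instead).
#'
#' @inheritParams selection_ratios
#' @param n_reps number of randomizations (default 9999).
#' @param seed RNG seed (required for reproducibility).
#' @param tail `"two"` (default), `"low"`, or `"high"`.
#' @return a `selectivity_test`: the [selection_ratios()] table plus
#'   `p_value`, with the null summary in attributes.
#' @export
monte_carlo_sigma_test <- function(counts, areas, n_reps = 9999,
                                   seed = 1L, tail = c("two", "low", "high")) {
  tail <- match.arg(tail)
  if (n_reps < 1) stop("n_reps must be >= 1")
  tab <- selection_ratios(counts, areas)
  N <- sum(tab$n_fires)
  set.seed(seed)
  draws <- stats::rmultinom(n_reps, N, tab$rel_area)   # zones x reps
  sig_null <- (draws / N) / tab$rel_area
  p <- vapply(seq_len(nrow(tab)), function(i) {
    le <- sum(sig_null[i, ] <= tab$sigma[i])
    ge <- sum(sig_null[i, ] >= tab$sigma[i])
    switch(tail,
           two = perm_p_two_tailed(le, ge, n_reps),
           low = (le + 1) / (n_reps + 1),
           high = (ge + 1) / (n_reps + 1))
  }, numeric(1))
  tab$p_value <- p
  structure(tab,
            null_mean = rowMeans(sig_null), null_sd = apply(sig_null, 1, stats::sd),
            n_reps = n_reps, seed = seed, tail = tail,
            class = c("selectivity_test", "data.frame"))
}

#' @export
print.selectivity_test <- function(x, ...) {
  cat(sprintf("Monte Carlo fire-selectivity test (%d randomizations, %s-tailed)\n",
              attr(x, "n_reps"), attr(x, "tail")))
  df <- as.data.frame(x)
  df$sigma <- round(df$sigma, 3)
  df$p_value <- format.pval(df$p_value, digits = 3, eps = 1e-4)
  print(df[, c("zone", "n_fires", "area", "sigma", "p_value")],
        row.names = FALSE)
  invisible(x)
}

anova_f <- function(y, g) {
  # classical one-way F from definitional sums of squares
  g <- as.factor(g)
  n <- length(y); k <- nlevels(g)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ni <- tabulate(g)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' One-way permutational ANOVA on per-unit selection ratios
#'
#' The F statistic is the classical between/within variance ratio of the
#' per-unit selection ratios across classes; its p-value is obtained by
#' uniformly permuting the class labels over units (`one-tailed`:
#' large F is extreme), with add-one continuity.
#'
#' @param sigma numeric vector of per-unit selection ratios.
#' @param labels class label per unit (>= 2 classes, each non-empty, and
#'   residual degrees of freedom > 0).
#' @param n_perms number of permutations (default 9999).
#' @param seed RNG seed.
#' @return a `perm_anova`: list with `F_observed`, `p_value`,
#'   `group_means`, `n_perms`, `seed`.
#' @export
permutation_anova <- function(sigma, labels, n_perms = 9999, seed = 1L) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (length(sigma) != length(labels)) stop("sigma and labels differ in length")
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(tabulate(labels) == 0L)) stop("empty class")
  if (length(sigma) - nlevels(labels) < 1L)
    stop("no residual degrees of freedom")
  if (n_perms < 1) stop("n_perms must be >= 1")
  F_obs <- anova_f(sigma, labels)
  set.seed(seed)
  F_null <- vapply(seq_len(n_perms),
                   function(i) anova_f(sigma, sample(labels)), numeric(1))
  p <- (sum(F_null >= F_obs) + 1) / (n_perms + 1)
  structure(list(F_observed = F_obs, p_value = p,
                 group_means = tapply(sigma, labels, mean),
                 group_n = tabulate(labels),
                 n_perms = n_perms, seed = seed),
            class = "perm_anova")
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf("Permutational one-way ANOVA: F = %.4g, p = %s (%d permutations)\n",
              x$F_observed,
              format.pval(x$p_value, digits = 3, eps = 1e-4), x$n_perms))
  cat("group means of sigma:\n")
  print(round(x$group_means, 3))
  invisible(x)
}

#' A-posteriori pairwise permutational F tests
#'
#' [permutation_anova()] restricted to every unordered pair of classes,
#' with no multiplicity adjustment. Each pair uses an independent
#' permutation stream derived from `seed`. Pairs with fewer than 3 units
#' in total are flagged not-testable (`NA` entries).
#'
#' @inheritParams permutation_anova
#' @return a `pairwise_f`: list of matrices `F` and `p` (classes x
#'   classes, lower triangle filled).
#' @export
pairwise_permutation_f <- function(sigma, labels, n_perms = 9999, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  lv <- levels(labels)
  k <- length(lv)
  if (k < 2L) stop("need at least 2 classes")
  Fm <- pm <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  pair_i <- 0L
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    pair_i <- pair_i + 1L
    sel <- labels %in% c(lv[i], lv[j])
    if (sum(sel) < 3L) next
    res <- permutation_anova(sigma[sel], labels[sel], n_perms,
                             seed = seed + pair_i)
    Fm[j, i] <- res$F_observed
    pm[j, i] <- res$p_value
  }
  structure(list(F = Fm, p = pm, n_perms = n_perms, seed = seed),
            class = "pairwise_f")
}

#' @export
print.pairwise_f <- function(x, ...) {
  cat(sprintf("Pairwise permutational F (%d permutations)\n", x$n_perms))
  cat("F:\n"); print(round(x$F, 3), na.print = "-")
  cat("p:\n"); print(round(x$p, 4), na.print = "-")
  invisible(x)
}
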