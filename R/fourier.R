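# Temporal Fourier analysis of seasonal NDVI profiles.
#
# The season is an N-sample periodic signal; we keep the additive term A0
# (series mean, a proxy for seasonal productivity) and the amplitudes of the
# first two harmonics A1 (one cycle per season) and A2 (two cycles), which
# summarize seasonality. Phases are discarded. Normalization is fixed so a
# unit-amplitude cosine yields A1 = 1 and the additive term is the plain
# mean: A0 = (1/N) sum x_t, A_k = sqrt(a_k^2 + b_k^2) with
# a_k = (2/N) sum x_t cos(2 pi k t / N), b_k = (2/N) sum x_t sin(2 pi k t / N),
# t = 0..N-1.

#' Mean seasonal NDVI profile per pixel
#'
#' Averages each composite index over years, ignoring masked observations.
#' A pixel is kept only if every composite index has at least
#' `min_years_valid` unmasked years; otherwise it is dropped from the valid
#' mask (its profile would mix different year subsets across the season).
#'
#' @param stack an `ndvi_stack` (array year x composite x pixel).
#' @param min_years_valid minimum unmasked years per composite; default
#'   `ceiling(n_years / 2)`.
#' @return a `mean_profile`: matrix composite x pixel with attributes
#'   `valid` (logical per pixel), `grid`, `composite_days`.
#' @export
mean_seasonal_profile <- function(stack,
                                  min_years_valid = ceiling(dim(stack)[1] / 2)) {
  stopifnot(inherits(stack, "ndvi_stack"))
  vals <- unclass(stack)
  nobs <- colSums(!is.na(vals), dims = 1L)        # composite x pixel
  prof <- colMeans(vals, na.rm = TRUE, dims = 1L) # composite x pixel
  prof[nobs == 0L] <- NA_real_
  valid <- colSums(nobs >= min_years_valid) == dim(vals)[2]
  if (!any(valid))
    stop("no pixel has >= ", min_years_valid,
         " valid years at every composite; inspect the nodata masks")
  prof[, !valid] <- NA_real_
  structure(prof, valid = valid,
            grid = attr(stack, "grid"),
            composite_days = attr(stack, "composite_days"),
            class = "mean_profile")
}

#' Fourier additive term and first two harmonic amplitudes of one profile
#'
#' @param x numeric vector of N >= 5 seasonal values, no missing values
#'   (masking is resolved upstream in [mean_seasonal_profile()]).
#' @return named numeric `c(A0, A1, A2)`.
#' @examples
#' t <- 0:10
#' tfa_vector(0.2 + 0.1 * cos(2 * pi * t / 11))  # A0 = 0.2, A1 = 0.1, A2 = 0
#' @export
tfa_vector <- function(x) {
  N <- length(x)
  if (N < 5L) stop("need at least 5 samples to resolve two harmonics")
  if (anyNA(x)) stop("profile contains missing values")
  t <- seq_len(N) - 1
  amp <- vapply(1:2, function(k) {
    a <- 2 / N * sum(x * cos(2 * pi * k * t / N))
    b <- 2 / N * sum(x * sin(2 * pi * k * t / N))
    sqrt(a * a + b * b)
  }, numeric(1))
  c(A0 = mean(x), A1 = amp[1], A2 = amp[2])
}

#' Fourier image from a mean-profile image
#'
#' Applies the per-profile decomposition to every valid pixel; masked
#' pixels stay masked.
#'
#' @param profiles a `mean_profile` from [mean_seasonal_profile()].
#' @return a `fourier_image`: array nrow x ncol x 3 (bands A0, A1, A2)
#'   with attributes `grid` and `valid`.
#' @export
tfa_image <- function(profiles) {
  stopifnot(inherits(profiles, "mean_profile"))
  valid <- attr(profiles, "valid")
  if (!any(valid)) stop("no valid pixels")
  g <- attr(profiles, "grid")
  vals <- unclass(profiles)
  N <- nrow(vals)
  t <- seq_len(N) - 1
  A0 <- colMeans(vals)
  band <- function(k) {
    a <- 2 / N * colSums(vals * cos(2 * pi * k * t / N))
    b <- 2 / N * colSums(vals * sin(2 * pi * k * t / N))
    sqrt(a * a + b * b)
  }
  out <- array(c(A0, band(1), band(2)), dim = c(g$nrow, g$ncol, 3),
               dimnames = list(NULL, NULL, c("A0", "A1", "A2")))
  if (any(!valid)) {
    bad <- which(!valid)
    for (b3 in 1:3) out[bad + (b3 - 1L) * g$nrow * g$ncol] <- NA_real_
  }
  structure(out, grid = g, valid = valid, class = "fourier_image")
}

#' @export
print.fourier_image <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<fourier_image> %d x %d pixels, %d valid\n",
              g$nrow, g$ncol, sum(attr(x, "valid"))))
  for (b in c("A0", "A1", "A2")) {
    v <- x[, , b]
    cat(sprintf("  %s: [%.4f, %.4f]\n", b,
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

# band as plain matrix
fourier_band <- function(fi, band) {
  m <- fi[, , band]
  dim(m) <- dim(fi)[1:2]
  m
}

# multi-band image -> npix x B matrix in column-major pixel order
fourier_matrix <- function(fi) {
  g <- attr(fi, "grid")
  B <- if (length(dim(fi)) == 3L) dim(fi)[3] else 1L
  bands <- dimnames(fi)[[3]]
  if (is.null(bands)) bands <- paste0("A", seq_len(B) - 1L)
  matrix(as.vector(unclass(fi)), g$nrow * g$ncol, B,
         dimnames = list(NULL, bands))
}
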