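# helper: wrap a plain matrix/array as a fourier-like image for segmentation
as_seg_image <- function(a, cellsize = 1) {
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  structure(a, grid = list(xll = 0, yll = 0, cellsize = cellsize,
                           nrow = dim(a)[1], ncol = dim(a)[2]),
            valid = !is.na(a[, , 1]), class = "fourier_image")
}

test_that("merge cost matches hand evaluation and brute-force recomputation", {
  p0 <- seg_params(scale = 1, shape_weight = 0, band_weights = 1,
                   min_pixels = 1)
  s_a <- segment_state(matrix(0.7), cbind(1, 1))
  s_b <- segment_state(matrix(0.7), cbind(1, 2))
  expect_equal(merge_cost(s_a, s_b, p0), 0)

  # values 0 and 1: merged sd = 0.5 over n = 2 -> cost = 2 * 0.5 = 1
  s0 <- segment_state(matrix(0), cbind(1, 1))
  s1 <- segment_state(matrix(1), cbind(1, 2))
  expect_equal(merge_cost(s0, s1, p0), 1)

  # running-sum state equals recomputation from raw pixel lists
  set.seed(33)
  pfull <- seg_params(scale = 1, shape_weight = 0.2,
                      compactness_weight = 0.8, band_weights = c(1, 1, 1),
                      min_pixels = 1)
  for (rep in 1:5) {
    # values indexed by pixel linear index on a 3 x 2 grid
    vals <- matrix(runif(18), 6, 3)
    co <- cbind(c(1, 1, 2, 2, 3, 3), c(1, 2, 1, 2, 1, 2))
    px <- co[, 1] + (co[, 2] - 1L) * 3L
    i1 <- 1:3; i2 <- 4:6
    s1 <- segment_state(vals[px[i1], ], co[i1, ])
    s2 <- segment_state(vals[px[i2], ], co[i2, ])
    shared <- oracle_shared_edges(px[i1], px[i2], 3L)
    got <- merge_cost(s1, s2, pfull, shared_edges = shared)
    ref <- oracle_cost(oracle_seg_stats(px[i1], vals, 3L),
                       oracle_seg_stats(px[i2], vals, 3L),
                       vals, 3L, pfull)
    expect_equal(got, ref, tolerance = 1e-9)
  }
  expect_error(merge_cost(s0, s1, p0, shared_edges = 0), "adjacent")
})

test_that("degenerate images collapse or stay apart as forced", {
  flat <- as_seg_image(matrix(0.5, 6, 6))
  lab <- segment_image(flat, seg_params(scale = 3, band_weights = 1,
                                        min_pixels = 1))
  expect_equal(length(unique(as.vector(lab))), 1L)

  blocks <- as_seg_image(cbind(matrix(0, 6, 3), matrix(1000, 6, 3)))
  lab2 <- segment_image(blocks, seg_params(scale = 1, band_weights = 1,
                                           min_pixels = 1))
  expect_equal(length(unique(as.vector(lab2))), 2L)
  expect_equal(length(unique(as.vector(lab2)[1:18])), 1L)
})

test_that("the merger reproduces a raw-pixel-list simulation of the rule", {
  set.seed(55)
  cases <- list(
    list(nr = 3, nc = 3, B = 1, scale = 0.6, sw = 0),
    list(nr = 3, nc = 3, B = 1, scale = 1.2, sw = 0.2),
    list(nr = 3, nc = 3, B = 2, scale = 0.8, sw = 0.3),
    list(nr = 4, nc = 4, B = 1, scale = 0.9, sw = 0.2),
    list(nr = 2, nc = 4, B = 3, scale = 0.7, sw = 0.4))
  for (cs in cases) {
    vals <- matrix(runif(cs$nr * cs$nc * cs$B), ncol = cs$B)
    params <- seg_params(scale = cs$scale, shape_weight = cs$sw,
                         compactness_weight = 0.8,
                         band_weights = rep(1, cs$B), min_pixels = 1)
    img <- as_seg_image(array(vals, dim = c(cs$nr, cs$nc, cs$B)))
    got <- as.vector(segment_image(img, params, enforce_min = FALSE))
    ref <- fnea_oracle(vals, cs$nr, cs$nc, params)
    expect_equal(got, ref)
  }
})

test_that("running statistics are conserved across all merges", {
  set.seed(77)
  vals <- array(runif(10 * 8 * 3), dim = c(10, 8, 3))
  vals[3, 4, ] <- NA                      # a nodata hole
  img <- as_seg_image(vals)
  lab <- segment_image(img, seg_params(scale = 0.8, min_pixels = 1),
                       enforce_min = FALSE)
  audit <- attr(lab, "audit")
  m <- matrix(as.vector(vals), ncol = 3)
  valid <- stats::complete.cases(m)
  expect_equal(sum(audit$seg_n), sum(valid))
  expect_equal(colSums(audit$seg_sum), colSums(m[valid, ]),
               tolerance = 1e-9)
  expect_equal(colSums(audit$seg_sumsq), colSums(m[valid, ]^2),
               tolerance = 1e-9)
  # per-segment running stats match recomputation from the label map
  labv <- as.vector(lab)
  ord <- order(audit$seg_id)
  for (s in seq_along(audit$seg_id)) {
    px <- which(labv == match(audit$seg_id[ord[s]],
                              sort(audit$seg_id)))
    expect_equal(audit$seg_n[ord[s]], length(px))
    expect_equal(audit$seg_sum[ord[s], ], colSums(m[px, , drop = FALSE]),
                 tolerance = 1e-9)
  }
  # nodata pixel is unlabeled
  expect_true(is.na(labv[3 + (4 - 1) * 10]))
})

test_that("a larger scale never yields more units", {
  set.seed(88)
  cfg <- scene_config(30, 30, four_class_specs(), n_years = 4,
                      noise_sd = 0.03, patch_seed = 6, n_fires = 10)
  fi <- tfa_image(mean_seasonal_profile(generate_ndvi_stack(
    generate_class_map(cfg), cfg)))
  prev <- Inf
  for (sc in c(0.5, 1, 2, 4, 8)) {
    n <- nrow(attr(segment_image(fi, seg_params(scale = sc,
                                                min_pixels = 1)),
                   "units"))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("the zero-noise block scene is recovered exactly over a wide scale range", {
  sc <- zero_noise_scene(40, 40)
  fi <- tfa_image(mean_seasonal_profile(sc$stack))
  # the upper end is bounded by the smallest between-block contrast: with
  # 40 x 10 strips the cheapest cross-block merge costs ~84, i.e. scale ~9
  for (scale in c(0.3, 1, 3, 8)) {
    lab <- segment_image(fi, seg_params(scale = scale, shape_weight = 0,
                                        min_pixels = 25))
    expect_equal(nrow(attr(lab, "units")), 4L)
    expect_equal(adjusted_rand(as.vector(lab), as.vector(sc$class_map)), 1)
  }
})

test_that("minimum-size cleanup absorbs small units and is a fixed point", {
  # a 1-pixel intrusion closer in value to the left block
  m <- cbind(matrix(0, 5, 3), matrix(10, 5, 3))
  m[3, 4] <- 1                            # right-block pixel, left-like value
  img <- as_seg_image(m)
  p <- seg_params(scale = 0.5, shape_weight = 0, band_weights = 1,
                  min_pixels = 3)
  lab <- segment_image(img, p, enforce_min = FALSE)
  expect_equal(length(unique(as.vector(lab))), 3L)
  fixed <- enforce_min_size(lab, img, p)
  u <- attr(fixed, "units")
  expect_true(all(u$n_pixels >= 3))
  # absorbed into the left (value-0) unit
  labm <- matrix(as.vector(fixed), 5, 6)
  expect_equal(labm[3, 4], labm[3, 3])
  # idempotence
  again <- enforce_min_size(fixed, img, p)
  expect_identical(as.vector(again), as.vector(fixed))

  set.seed(99)
  noisy <- as_seg_image(array(runif(8 * 8 * 2), dim = c(8, 8, 2)))
  p2 <- seg_params(scale = 0.6, band_weights = c(1, 1), min_pixels = 4)
  l2 <- segment_image(noisy, p2)
  expect_true(all(attr(l2, "units")$n_pixels >= 4))
  l3 <- enforce_min_size(l2, noisy, p2)
  expect_identical(as.vector(l3), as.vector(l2))
})
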