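toy_features <- function(a0) {
  data.frame(unit_id = seq_along(a0), n_pixels = 10,
             area_km2 = 10 * 0.0625, mean_A0 = a0,
             mean_A1 = 0, mean_A2 = 0,
             x = seq_along(a0), y = 0)
}

test_that("unit features are per-unit means with correct areas", {
  a <- array(0, dim = c(1, 2, 3),
             dimnames = list(NULL, NULL, c("A0", "A1", "A2")))
  a[1, , 1] <- c(0.2, 0.4); a[1, , 2] <- c(0.1, 0.3); a[1, , 3] <- 0
  fi <- structure(a, grid = list(xll = 0, yll = 0, cellsize = 250,
                                 nrow = 1, ncol = 2),
                  valid = c(TRUE, TRUE), class = "fourier_image")
  lab <- pheno_grid(matrix(1L, 1, 2), cellsize = 250)
  u <- unit_features(lab, fi)
  expect_equal(u$mean_A0, 0.3)
  expect_equal(u$mean_A1, 0.2)
  expect_equal(u$n_pixels, 2L)
  expect_equal(u$area_km2, 2 * 0.0625)   # 250 m pixels

  sc <- zero_noise_scene(20, 20)
  fi2 <- tfa_image(mean_seasonal_profile(sc$stack))
  lab2 <- segment_image(fi2, seg_params(scale = 1, shape_weight = 0,
                                        min_pixels = 25))
  u2 <- attr(lab2, "units")
  truth <- do.call(rbind, lapply(sc$config$class_specs, function(s)
    c(s$base_level, s$amp1, s$amp2)))
  got <- as.matrix(u2[, c("mean_A0", "mean_A1", "mean_A2")])
  # each unit is one generator block; match on A0
  cls <- apply(got, 1, function(r) which.min(abs(truth[, 1] - r[1])))
  expect_equal(got, truth[cls, ], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("UPGMA reproduces hand-computed merges and heights", {
  # pairwise distances d(A,B) = 1, d(A,C) = 5, d(B,C) = 4
  f <- toy_features(c(0, 1, 5))
  hc <- upgma_linkage(f)
  expect_equal(sort(hc$height), c(1, 4.5))
  cut2 <- cut_to_classes(hc, 2, f)
  expect_equal(as.integer(cut2$pfc[1] == cut2$pfc[2]), 1L)
  expect_false(cut2$pfc[3] == cut2$pfc[1])

  f2 <- toy_features(c(0.2, 0.9))
  hc2 <- upgma_linkage(f2)
  expect_equal(hc2$height, 0.7, tolerance = 1e-12)
})

test_that("cophenetic distances match a recursive average-linkage oracle", {
  set.seed(202)
  f <- data.frame(unit_id = 1:6, n_pixels = 5, area_km2 = 1,
                  mean_A0 = runif(6), mean_A1 = runif(6),
                  mean_A2 = runif(6), x = runif(6), y = runif(6))
  hc <- upgma_linkage(f)
  expect_true(all(diff(hc$height) >= -1e-12))   # UPGMA monotone
  got <- as.matrix(stats::cophenetic(hc))
  ref <- upgma_oracle_cophenetic(
    as.matrix(f[, c("mean_A0", "mean_A1", "mean_A2")]))
  dimnames(ref) <- dimnames(got)
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("dendrogram cuts nest and order classes by seasonality", {
  set.seed(203)
  f <- data.frame(unit_id = 1:8, n_pixels = 5, area_km2 = 1,
                  mean_A0 = runif(8), mean_A1 = runif(8),
                  mean_A2 = runif(8), x = runif(8), y = runif(8))
  hc <- upgma_linkage(f)
  expect_equal(nlevels(cut_to_classes(hc, 1, f)$pfc), 1L)
  all_own <- cut_to_classes(hc, 8, f)
  expect_equal(length(unique(all_own$pfc)), 8L)
  expect_error(cut_to_classes(hc, 0, f), "k must be")
  for (k in 3:5) {
    fine <- cut_to_classes(hc, k, f)$pfc
    coarse <- cut_to_classes(hc, k - 1, f)$pfc
    # nesting: units sharing a fine class share the coarse class
    tab <- table(fine, coarse)
    expect_true(all(rowSums(tab > 0) == 1))
  }
  cut3 <- cut_to_classes(hc, 3, f)
  a1 <- tapply(f$mean_A1, cut3$pfc, mean)
  expect_true(all(diff(a1[paste0("PFC", 1:3)]) <= 0))
})

test_that("the spatial split recovers separated blobs deterministically", {
  set.seed(204)
  blob1 <- cbind(rnorm(6, 0, 0.2), rnorm(6, 0, 0.2))
  blob2 <- cbind(rnorm(6, 10, 0.2), rnorm(6, 10, 0.2))
  f <- data.frame(unit_id = 1:13, n_pixels = 5, area_km2 = 1,
                  mean_A0 = c(rep(0.3, 12), 0.9),
                  mean_A1 = c(rep(0.2, 12), 0.01),
                  mean_A2 = 0.05,
                  x = c(blob1[, 1], blob2[, 1], 20),
                  y = c(blob1[, 2], blob2[, 2], 20))
  hc <- upgma_linkage(f)
  asg <- cut_to_classes(hc, 2, f)
  split1 <- split_largest_spatial(asg, f, seed = 5)
  split2 <- split_largest_spatial(asg, f, seed = 5)
  expect_identical(split1$pfc, split2$pfc)
  expect_equal(nlevels(split1$pfc), 3L)
  sub <- split1$pfc[1:12]
  expect_equal(length(unique(sub[1:6])), 1L)
  expect_equal(length(unique(sub[7:12])), 1L)
  expect_false(sub[1] == sub[7])

  degen <- f
  degen$x <- 1; degen$y <- 1
  expect_error(split_largest_spatial(asg, degen, seed = 5), "degenerate")
  one <- toy_features(c(0, 10))
  asg1 <- cut_to_classes(upgma_linkage(one), 2, one)
  expect_error(split_largest_spatial(asg1, one), "single unit")
})
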