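test_that("class maps honor the requested layout", {
  one <- scene_config(7, 9, list(pheno_class_spec(1, 0.5)), n_fires = 10)
  expect_true(all(generate_class_map(one) == 1L))

  two <- scene_config(10, 10, four_class_specs()[1:2], n_fires = 10,
                      layout = "blocks")
  cm <- generate_class_map(two)
  expect_true(all(cm[, 1:5] == 1L))
  expect_true(all(cm[, 6:10] == 2L))

  seeded <- scene_config(30, 30, four_class_specs(), layout = "seeded",
                         patch_seed = 11, n_fires = 10)
  m1 <- generate_class_map(seeded)
  m2 <- generate_class_map(seeded)
  expect_identical(unclass(m1), unclass(m2))
  expect_setequal(unique(as.vector(m1)), 1:4)
})

test_that("impossible scenes are rejected with informative errors", {
  cfg <- scene_config(3, 2, four_class_specs(), n_fires = 10,
                      layout = "blocks")
  expect_error(generate_class_map(cfg), "classes")
  expect_error(pheno_class_spec(1, 0.9, amp1 = 0.3), "\\[-1, 1\\]")
  expect_error(scene_config(4, 4, four_class_specs(), n_composites = 4),
               "n_composites")
  zero <- scene_config(4, 4, list(pheno_class_spec(1, 0.5,
                                                   fire_multiplier = 0)),
                       n_fires = 10)
  expect_error(generate_ignitions(generate_class_map(zero), zero),
               "multipliers")
  none <- scene_config(4, 4, list(pheno_class_spec(1, 0.5)), n_fires = 0)
  expect_error(generate_ignitions(generate_class_map(none), none),
               "n_fires")
})

test_that("stacks are deterministic, clipped, and flat when degenerate", {
  cfg <- scene_config(6, 6, list(pheno_class_spec(1, 0.5)), n_years = 3,
                      noise_sd = 0, year_effect_sd = 0, n_fires = 10)
  cm <- generate_class_map(cfg)
  st <- generate_ndvi_stack(cm, cfg)
  expect_true(all(st == 0.5))

  noisy <- scene_config(6, 6, four_class_specs(), n_years = 4,
                        noise_sd = 0.05, patch_seed = 3, n_fires = 10)
  cmn <- generate_class_map(noisy)
  s1 <- generate_ndvi_stack(cmn, noisy)
  s2 <- generate_ndvi_stack(cmn, noisy)
  expect_identical(unclass(s1), unclass(s2))
  expect_true(all(s1 >= -1 & s1 <= 1))
})

test_that("averaging years shrinks profile noise like 1/n_years", {
  cfg <- scene_config(5, 5, list(pheno_class_spec(1, 0.5)), n_years = 200,
                      noise_sd = 0.1, year_effect_sd = 0, patch_seed = 9,
                      n_fires = 10)
  st <- generate_ndvi_stack(generate_class_map(cfg), cfg)
  prof <- mean_seasonal_profile(st, min_years_valid = 1)
  # each profile entry is a mean of 200 iid N(0.5, 0.1) draws
  v <- stats::var(as.vector(prof))
  expect_lt(abs(v - 0.1^2 / 200), 0.5 * 0.1^2 / 200)
})

test_that("fire placement matches the designed selectivity", {
  cfg <- scene_config(10, 10, list(
    pheno_class_spec(1, 0.4, fire_multiplier = 3),
    pheno_class_spec(2, 0.6, fire_multiplier = 1)),
    layout = "blocks", n_fires = 4000, fire_seed = 21)
  cm <- generate_class_map(cfg)
  fires <- generate_ignitions(cm, cfg)
  expect_identical(generate_ignitions(cm, cfg)$x, fires$x)
  expect_equal(nrow(fires), 4000)
  # every point inside the extent
  rc <- cell_from_xy(cm, fires$x, fires$y)
  expect_false(anyNA(rc$row))

  counts <- count_fires_per_zone(cm, fires)
  sig <- selection_ratios(counts, c(50, 50))$sigma
  truth <- c(1.5, 0.5)
  p <- c(0.75, 0.25)
  se <- sqrt(p * (1 - p) / 4000) / 0.5   # sd of sigma-hat per class
  expect_true(all(abs(sig - truth) <= 3 * se))
})

test_that("implied true selection ratios average to 1 over area", {
  cfg <- scene_config(12, 12, four_class_specs(), layout = "seeded",
                      patch_seed = 5, n_fires = 10)
  cm <- generate_class_map(cfg)
  sig <- true_selection_ratios(cm, cfg)
  rel <- tabulate(as.vector(cm), 4) / length(cm)
  expect_equal(sum(rel * sig), 1, tolerance = 1e-12)
})

test_that("covariate maps follow the class map with optional label noise", {
  cfg <- scene_config(10, 10, four_class_specs(), n_fires = 10)
  cm <- generate_class_map(cfg)
  cov0 <- generate_covariate_map(cm, cfg, label_noise = 0)
  labs <- c(1L, 2L, 2L, 3L)
  expect_identical(as.vector(cov0), labs[as.vector(cm)])
  cov1 <- generate_covariate_map(cm, cfg, label_noise = 0.3, seed = 4)
  expect_identical(unclass(generate_covariate_map(cm, cfg, 0.3, seed = 4)),
                   unclass(cov1))
  expect_gt(mean(as.vector(cov1) != labs[as.vector(cm)]), 0.05)
})
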