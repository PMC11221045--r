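test_that("benthoscape generation hits target proportions and is seeded", {
  cfg <- sim_config(seed = 1)
  r <- generate_benthoscape(cfg)
  cp <- class_proportions(r)
  realized <- setNames(cp$proportion, as.character(cp$class))
  for (lv in names(cfg$target_props)) {
    expect_lt(abs(realized[[lv]] - cfg$target_props[[lv]]), 0.03)
  }
  expect_identical(generate_benthoscape(cfg)$values, r$values)
})

test_that("a single-class target yields a uniform raster", {
  cfg <- sim_config(n_rows = 40, n_cols = 40,
                    target_props = c(deep_silt_mud = 1), seed = 3)
  r <- generate_benthoscape(cfg)
  expect_true(all(r$values == 3L))
})

test_that("proportions not summing to one are rejected", {
  expect_error(sim_config(target_props = c(coarse_sediment = 0.5,
                                           nodata = 0.4)),
               "sum to 1")
})

test_that("track simulation respects degenerate and concentrated limits", {
  r <- uniform_raster(4L, n = 200)
  # zero steps: the single start point
  tr0 <- simulate_track(r, beta = c(), shape = 1.5, scale = 3, kappa = 1,
                        start = c(100, 100), n_steps = 0, seed = 1)
  expect_equal(nrow(tr0), 1)
  # high concentration: nearly straight movement
  tr <- simulate_track(r, beta = c(), shape = 1.5, scale = 2, kappa = 50,
                       start = c(100, 100), n_steps = 400, seed = 2)
  b <- atan2(diff(tr$y), diff(tr$x))
  ta <- diff(b)
  ta <- atan2(sin(ta), cos(ta))
  expect_gt(mean(cos(ta)), 0.95)
  # determinism
  tr2 <- simulate_track(r, beta = c(), shape = 1.5, scale = 2, kappa = 50,
                        start = c(100, 100), n_steps = 400, seed = 2)
  expect_identical(tr$x, tr2$x)
  expect_error(
    simulate_track(r, beta = c(), shape = 1.5, scale = 3, kappa = 1,
                   start = c(500, 100), n_steps = 1),
    "outside the raster")
})

test_that("without selection the movement kernel passes goodness of fit", {
  # large uniform raster so boundary rejection never distorts the kernel
  r <- bentho_raster(matrix(4L, 400, 400), 0, 0, 10)
  shape <- 1.5; scale <- 3; kappa <- 1
  tr <- simulate_track(r, beta = c(), shape = shape, scale = scale,
                       kappa = kappa, start = c(2000, 2000),
                       n_steps = 10000, seed = 9)
  sl <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  b <- atan2(diff(tr$y), diff(tr$x))
  ta <- atan2(sin(diff(b)), cos(diff(b)))
  expect_gt(stats::ks.test(sl, stats::pgamma, shape = shape,
                           scale = scale)$p.value, 0.01)
  expect_gt(stats::ks.test(ta, function(q) pvonmises(q, kappa))$p.value,
            0.01)
})

test_that("observation with zero error reproduces the interpolated truth", {
  r <- uniform_raster(4L, n = 200)
  tr <- simulate_track(r, beta = c(), shape = 1.5, scale = 3, kappa = 1,
                       start = c(100, 100), n_steps = 50, seed = 4)
  cfg <- sim_config(sigma0 = 0, detection_prob = 1, seed = 5)
  fx <- observe_track(tr, cfg, seed = 5)
  expect_equal(fx$x, fx$true_x)
  expect_equal(fx$y, fx$true_y)
  # transmission intervals within the schedule bounds
  gaps <- diff(fx$t)
  expect_true(all(gaps >= cfg$transmission_lo - 1e-9))
  expect_true(all(gaps <= cfg$transmission_hi + 1e-9))
})

test_that("default error calibration gives a median error near 2.4 m", {
  r <- uniform_raster(4L, n = 200)
  cfg <- sim_config(seed = 6)
  sy <- generate_sync_tags(r, n = 16, cfg, n_fixes = 700, seed = 6)
  expect_gte(nrow(sy), 10000)
  med <- median(sy$hpem)
  expect_gte(med, 2.0)
  expect_lte(med, 2.8)
  # HPE is an informative but imperfect proxy for the true error
  expect_gt(cor(sy$hpe, sy$hpem, method = "spearman"), 0.5)
  expect_lt(cor(sy$hpe, sy$hpem, method = "spearman"), 0.999)
})

test_that("sync tags sit at distinct positions and carry exact error", {
  r <- uniform_raster(4L, n = 100)
  cfg0 <- sim_config(sigma0 = 0, seed = 8)
  sy <- generate_sync_tags(r, n = 16, cfg0, n_fixes = 5, seed = 8)
  expect_equal(length(unique(paste(sy$true_x, sy$true_y))), 16)
  expect_true(all(sy$hpem == 0))
  sy2 <- generate_sync_tags(r, n = 16, cfg0, n_fixes = 5, seed = 8)
  expect_identical(sy$x, sy2$x)
})

test_that("positions CSV round-trips the fix schema", {
  r <- uniform_raster(4L, n = 100)
  cfg <- sim_config(seed = 10)
  sy <- generate_sync_tags(r, n = 4, cfg, n_fixes = 10, seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_positions_csv(sy, path)
  back <- read_positions_csv(path)
  expect_equal(back$x, sy$x)
  expect_equal(back$t, sy$t, tolerance = 1e-3)  # ms precision on disk
  expect_identical(back$tag_id, sy$tag_id)
  expect_identical(back$is_sync, sy$is_sync)
})
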