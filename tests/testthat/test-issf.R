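test_that("strata hold one observed and n random steps sharing the start", {
  r <- uniform_raster(4L, n = 200)
  st <- sim_steps(r, beta = c(), n_steps = 120, seed = 71)
  kern <- fit_tentative_kernel(st)
  strata <- draw_random_steps(st, kern, n = 20, raster = r, seed = 72)
  sizes <- table(strata$stratum)
  expect_true(all(sizes == 21))
  cases <- tapply(strata$case, strata$stratum, sum)
  expect_true(all(cases == 1))
  n_obs <- sum(!is.na(st$ta) & is.finite(st$log_sl))
  expect_equal(length(sizes), n_obs)
  expect_true(all(strata$sl[!strata$case] > 0))
  expect_true(all(is.finite(strata$log_sl[!strata$case])))
  expect_error(draw_random_steps(st, list(), n = 20, raster = r),
               "bs_kernel")
})

test_that("random turning angles follow the tentative concentration", {
  r <- uniform_raster(4L, n = 200)
  st <- sim_steps(r, beta = c(), n_steps = 150, kappa = 2, seed = 73)
  kern <- fit_tentative_kernel(st)
  # force a near-degenerate concentration: angles hug zero
  kern$vonmises$kappa <- 500
  strata <- draw_random_steps(st, kern, n = 30, raster = r, seed = 74)
  expect_true(all(abs(strata$ta[!strata$case]) < 0.2))
})

test_that("random step lengths are draws from the tentative gamma", {
  r <- bentho_raster(matrix(4L, 300, 300), 0, 0, 10)
  st <- sim_steps(r, beta = c(), n_steps = 130, seed = 75)
  kern <- fit_tentative_kernel(st)
  strata <- draw_random_steps(st, kern, n = 100, raster = r, seed = 76)
  sl <- strata$sl[!strata$case]
  expect_gte(length(sl), 10000)
  expect_gt(stats::ks.test(sl, stats::pgamma, shape = kern$gamma$shape,
                           scale = kern$gamma$scale)$p.value, 0.01)
})

test_that("the design matrix matches the model formula term count", {
  r <- generate_benthoscape(sim_config(n_rows = 80, n_cols = 80,
                                       target_props = c(
                                         silt_mud_gravel = 0.4,
                                         mixed_sediment = 0.35,
                                         coarse_sediment = 0.25),
                                       patch_scale = 6, seed = 77))
  st <- sim_steps(r, beta = c(), n_steps = 400, seed = 78)
  kern <- fit_tentative_kernel(st)
  strata <- draw_random_steps(st, kern, n = 15, raster = r, seed = 79)
  des <- build_issf_design(strata)
  n_end <- length(unique(strata$end_class[!is.na(strata$end_class)]))
  n_start <- length(unique(strata$start_class))
  covs <- setdiff(names(des), c("case", "stratum"))
  expect_equal(length(covs),
               (n_end - 1) + 2 + 2 * (n_start - 1))
  # within-stratum-constant end class is flagged
  one <- strata[strata$stratum == strata$stratum[1], ]
  one$end_class <- factor("mixed_sediment", levels = substrate_levels())
  des1 <- build_issf_design(one)
  expect_true("mixed_sediment" %in% attr(des1, "inestimable"))
})

test_that("iSSF refuses individuals with too few strata", {
  r <- uniform_raster(4L, n = 200)
  st <- sim_steps(r, beta = c(), n_steps = 15, seed = 80)
  kern <- fit_tentative_kernel(st)
  strata <- draw_random_steps(st, kern, n = 10, raster = r, seed = 81)
  expect_error(fit_issf(strata, B = 20, min_strata = 20), "strata")
})

test_that("the full iSSF fit is deterministic given the seed", {
  r <- generate_benthoscape(sim_config(n_rows = 100, n_cols = 100,
                                       patch_scale = 8, seed = 82))
  st <- sim_steps(r, beta = c(mixed_sediment = 1), n_steps = 300,
                  seed = 83)
  kern <- fit_tentative_kernel(st)
  strata <- draw_random_steps(st, kern, n = 20, raster = r, seed = 84)
  f1 <- fit_issf(strata, B = 50, seed = 85)
  f2 <- fit_issf(strata, B = 50, seed = 85)
  expect_identical(f1$estimates, f2$estimates)
  expect_equal(f1$boot$n_converged, 50)
})

test_that("kernel updating adds the fitted movement coefficients", {
  kern <- structure(list(gamma = structure(list(shape = 2, scale = 3),
                                           class = "bs_gamma"),
                         vonmises = structure(list(mu = 0, kappa = 1),
                                              class = "bs_vonmises")),
                    class = "bs_kernel")
  # zero coefficients: identity
  est0 <- tibble::tibble(
    term = c("log_sl", "cos_ta", "start_mixed_sediment:log_sl",
             "start_mixed_sediment:cos_ta"),
    estimate = c(0, 0, 0, 0))
  up0 <- update_kernel(kern, est0)
  expect_equal(up0$shape, rep(2, 2))
  expect_equal(up0$kappa, rep(1, 2))
  # a mixed-sediment step-length interaction of 0.37 concentrates the
  # shape away from zero on that substrate
  est1 <- tibble::tibble(
    term = c("log_sl", "cos_ta", "start_mixed_sediment:log_sl",
             "start_mixed_sediment:cos_ta"),
    estimate = c(0, 0, 0.37, -0.49))
  up1 <- update_kernel(kern, est1)
  mixed <- up1[up1$start_class == "mixed_sediment", ]
  expect_equal(mixed$shape, 2.37)
  expect_equal(mixed$kappa, 0.51)
  expect_true(all(up1$valid))
  # a strongly negative correction invalidates the kernel
  est2 <- tibble::tibble(term = "log_sl", estimate = -2.5)
  up2 <- update_kernel(kern, est2)
  expect_false(up2$valid[1])
})

test_that("behavioural labels are a pure function of coefficient signs", {
  est <- tibble::tibble(
    term = c("end_mixed_sediment", "start_mixed_sediment:cos_ta",
             "start_deep_silt_mud:log_sl", "end_coarse_sediment"),
    estimate = c(0.8, -0.49, 1.51, 0))
  lab <- interpret_estimates(est)
  expect_match(lab$label[lab$term == "start_mixed_sediment:cos_ta"],
               "lower directionality")
  expect_match(lab$label[lab$term == "start_deep_silt_mud:log_sl"],
               "longer steps")
  expect_match(lab$label[lab$term == "end_mixed_sediment"],
               "selected over reference")
  expect_match(lab$label[lab$term == "end_coarse_sediment"],
               "no difference")
  # permuting rows never changes any label
  perm <- est[c(3, 1, 4, 2), ]
  lab2 <- interpret_estimates(perm)
  expect_equal(dplyr::arrange(lab, term)$label,
               dplyr::arrange(lab2, term)$label)
})
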