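mk_fixes <- function(t_min, tag = "a1") {
  tibble::tibble(tag_id = tag, t = t_min * 60,
                 x = seq_along(t_min), y = 0)
}

test_that("greedy resampling follows the declared burst rule", {
  fx <- mk_fixes(c(0, 3, 6, 9, 12, 20, 31))
  out <- resample_fixes(fx, rate = 600, tolerance = 120)
  expect_equal(out$t / 60, c(0, 9, 20, 31))
  expect_equal(length(unique(out$burst_id)), 1)
})

test_that("exactly regular fixes form one burst; sparse fixes form none", {
  reg <- mk_fixes(seq(0, 120, by = 10))
  out <- resample_fixes(reg)
  expect_equal(nrow(out), 13)
  expect_equal(length(unique(out$burst_id)), 1)
  sparse <- mk_fixes(seq(0, 300, by = 30))
  expect_equal(nrow(resample_fixes(sparse)), 0)
})

test_that("unsorted fixes are rejected", {
  fx <- mk_fixes(c(10, 0, 20))
  expect_error(resample_fixes(fx), "not time-sorted")
})

test_that("kept-fix gaps always lie within the tolerance window", {
  set.seed(21)
  t_s <- cumsum(runif(400, 60, 400))
  fx <- tibble::tibble(tag_id = "a1", t = t_s, x = rnorm(400), y = rnorm(400))
  out <- resample_fixes(fx, rate = 600, tolerance = 120)
  gaps <- out |>
    dplyr::group_by(.data$burst_id) |>
    dplyr::summarise(ok = all(diff(t) >= 480 & diff(t) <= 720) | dplyr::n() < 2)
  expect_true(all(gaps$ok))
  # steps count equals sum over bursts of (length - 1)
  steps <- build_steps(out)
  expected <- out |>
    dplyr::count(.data$burst_id) |>
    dplyr::summarise(n = sum(n - 1)) |>
    dplyr::pull(n)
  expect_equal(nrow(steps), expected)
})

test_that("angle wrapping lands in (-pi, pi] and is 2*pi periodic", {
  wrap <- benthoselect:::wrap_angle
  th <- seq(-10, 10, by = 0.037)
  w <- wrap(th)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(wrap(th + 2 * pi), w, tolerance = 1e-12)
  expect_equal(wrap(pi), pi)
  expect_equal(wrap(-pi), pi)
})

test_that("step lengths and turning angles follow from the geometry", {
  fx <- tibble::tibble(tag_id = "a1", burst_id = "a1_1",
                       t = c(0, 600, 1200),
                       x = c(0, 1, 1), y = c(0, 0, 1))
  st <- build_steps(fx)
  expect_equal(st$sl, c(1, 1))
  expect_true(is.na(st$ta[1]))
  expect_equal(st$ta[2], pi / 2)
  expect_equal(st$cos_ta[2], 0, tolerance = 1e-12)
  # collinear: zero turning angle
  fx2 <- tibble::tibble(tag_id = "a1", burst_id = "a1_1",
                        t = c(0, 600, 1200),
                        x = c(0, 1, 2), y = c(0, 0, 0))
  st2 <- build_steps(fx2)
  expect_equal(st2$ta[2], 0)
  expect_equal(st2$cos_ta[2], 1)
  # repeated point: zero step length, non-finite log
  fx3 <- tibble::tibble(tag_id = "a1", burst_id = "a1_1",
                        t = c(0, 600), x = c(0, 0), y = c(0, 0))
  st3 <- build_steps(fx3)
  expect_equal(st3$sl, 0)
  expect_true(!is.finite(st3$log_sl))
})

test_that("step filters remove non-finite log lengths and missing angles", {
  fx <- tibble::tibble(tag_id = "a1", burst_id = "a1_1",
                       t = seq(0, 3000, by = 600),
                       x = c(0, 1, 1, 1, 2, 3), y = c(0, 0, 1, 1, 1, 1))
  st <- build_steps(fx)     # 5 steps; one zero-length (fix 3 -> 4)
  expect_equal(nrow(st), 5)
  kept <- filter_steps(st, require_ta = FALSE)
  expect_equal(nrow(kept), 4)
  expect_equal(attr(kept, "counts")$nonfinite_log_sl, 1)
  kept2 <- filter_steps(st, require_ta = TRUE)
  expect_equal(attr(kept2, "counts")$missing_ta, 1)
  # a burst of 5 fixes gives 4 steps, 3 with computable angles
  fx5 <- tibble::tibble(tag_id = "a1", burst_id = "a1_1",
                        t = seq(0, 2400, by = 600),
                        x = cumsum(rep(1, 5)), y = c(0, 1, 0, 1, 0))
  st5 <- build_steps(fx5)
  expect_equal(nrow(st5), 4)
  expect_equal(sum(!is.na(st5$ta)), 3)
  # empty input
  empty <- filter_steps(st5[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "counts")$nonfinite_log_sl, 0)
})

test_that("covariates come from the endpoint cells only", {
  st <- tibble::tibble(tag_id = "a1", burst_id = "a1_1",
                       t_start = 0, t_end = 600,
                       x_start = 2, y_start = 2, x_end = 12, y_end = 2,
                       sl = 10, log_sl = log(10), bearing = 0,
                       ta = NA_real_, cos_ta = NA_real_)
  r <- tiny_raster()   # left column codes 0/2, right column 1/3 (south-up)
  out <- attach_covariates(st, r)
  expect_equal(as.character(out$start_class), "coarse_sediment")
  expect_equal(as.character(out$end_class), "silt_mud_gravel")
  # nodata endpoint keeps the nodata level
  rn <- bentho_raster(matrix(c(0L, NA), 1, 2), 0, 0, 10)
  stn <- st; stn$y_start <- 5; stn$y_end <- 5; stn$x_end <- 15
  outn <- attach_covariates(stn, rn)
  expect_equal(as.character(outn$end_class), "nodata")
  # outside the extent is an error
  sto <- st; sto$x_end <- 100
  expect_error(attach_covariates(sto, r), "outside raster bounds")
})
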