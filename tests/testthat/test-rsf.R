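square_presences <- function(tag = "a1", n_inner = 30, seed = 61) {
  set.seed(seed)
  tibble::tibble(
    tag_id = tag,
    x = c(1, 39, 39, 1, runif(n_inner, 5, 35)),
    y = c(1, 1, 39, 39, runif(n_inner, 5, 35))
  )
}

test_that("pseudo-absences fall inside the MCP at the requested ratio", {
  r <- uniform_raster(4L, n = 40)
  pres <- square_presences()
  ua <- draw_pseudo_absences(pres, r, ratio = 10, seed = 1)
  expect_equal(sum(ua$case), nrow(pres))
  expect_equal(sum(!ua$case), 10 * nrow(pres))
  ab <- ua[!ua$case, ]
  expect_true(all(ab$x >= 1 & ab$x <= 39 & ab$y >= 1 & ab$y <= 39))
  # uniform raster: every point carries the raster's single class
  expect_true(all(ua$class == "shallow_silt_mud"))
  # determinism
  ua2 <- draw_pseudo_absences(pres, r, ratio = 10, seed = 1)
  expect_identical(ua$x, ua2$x)
})

test_that("degenerate presence sets are rejected", {
  r <- uniform_raster(4L, n = 40)
  few <- tibble::tibble(tag_id = "a1", x = 1:4, y = 1:4)
  expect_error(draw_pseudo_absences(few, r), "fewer than 5")
  line <- tibble::tibble(tag_id = "a1", x = 1:6, y = (1:6) * 2)
  expect_error(draw_pseudo_absences(line, r), "collinear")
})

test_that("the subsample-refit scheme recovers known selection weights", {
  # presences drawn with relative weight 3 on mixed_sediment over a
  # two-class raster with equal availability
  m <- cbind(matrix(1L, 40, 20), matrix(2L, 40, 20))
  r <- bentho_raster(m, 0, 0, 1)
  set.seed(62)
  draw_weighted <- function(tag, n = 220, w = 3) {
    pts <- tibble::tibble(x = numeric(0), y = numeric(0))
    while (nrow(pts) < n) {
      cx <- runif(3 * n, 0.5, 39.5); cy <- runif(3 * n, 0.5, 39.5)
      cls <- extract_class(r, cx, cy)
      keep <- runif(3 * n) < ifelse(cls == "mixed_sediment", w, 1) / w
      pts <- dplyr::bind_rows(pts, tibble::tibble(x = cx[keep],
                                                  y = cy[keep]))
    }
    dplyr::mutate(pts[seq_len(n), ], tag_id = tag, .before = 1)
  }
  pres <- dplyr::bind_rows(lapply(paste0("id", 1:3), draw_weighted))
  ua <- draw_pseudo_absences(pres, r, ratio = 10, seed = 2)
  fit <- rsf_resample_fit(ua, reruns = 30, per_individual = 100, seed = 3)
  med <- median(fit$coefficients$estimate[
    fit$coefficients$term == "mixed_sediment"])
  expect_gt(med, log(3) - 0.25)
  expect_lt(med, log(3) + 0.25)
  # determinism of the rerun scheme
  fit2 <- rsf_resample_fit(ua, reruns = 30, per_individual = 100, seed = 3)
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("individuals without enough points are excluded with a warning", {
  m <- cbind(matrix(1L, 40, 20), matrix(4L, 40, 20))
  r <- bentho_raster(m, 0, 0, 1)
  pres <- dplyr::bind_rows(square_presences("a1", 120, seed = 63),
                           square_presences("a2", 120, seed = 64),
                           square_presences("a3", 10, seed = 65))
  ua <- draw_pseudo_absences(pres, r, ratio = 10, seed = 4)
  expect_warning(
    fit <- rsf_resample_fit(ua, reruns = 2, per_individual = 50, seed = 5),
    "a3")
  expect_error(
    suppressWarnings(
      rsf_resample_fit(ua[ua$tag_id %in% c("a1", "a3"), ],
                       reruns = 2, per_individual = 50, seed = 5)),
    "fewer than 2 usable")
})

test_that("single-class data are rejected as undefined selection", {
  r <- uniform_raster(4L, n = 40)
  pres <- dplyr::bind_rows(square_presences("a1", 120, seed = 68),
                           square_presences("a2", 120, seed = 69))
  ua <- draw_pseudo_absences(pres, r, ratio = 5, seed = 7)
  expect_error(rsf_resample_fit(ua, reruns = 2, per_individual = 50,
                                seed = 8),
               "fewer than 2 substrate classes")
})

test_that("relative selection strength summarizes and flags correctly", {
  draws <- tibble::tibble(
    rerun = rep(1:5, 3),
    term = rep(c("zero", "double", "straddle"), each = 5),
    estimate = c(rep(0, 5), rep(log(2), 5), c(-0.2, -0.1, 0, 0.1, 0.2))
  )
  rss <- relative_selection_strength(draws)
  expect_equal(rss$rss_median[rss$class == "zero"], 1)
  expect_equal(rss$rss_median[rss$class == "double"], 2)
  expect_false(rss$no_clear_selection[rss$class == "double"])
  expect_true(rss$no_clear_selection[rss$class == "straddle"])
})

test_that("the reference class has RSS identically one in every rerun", {
  r <- uniform_raster(1L, n = 40)   # the reference class itself
  pres <- dplyr::bind_rows(square_presences("a1", 120, seed = 66),
                           square_presences("a2", 120, seed = 67))
  ua <- draw_pseudo_absences(pres, r, ratio = 5, seed = 6)
  # single-class data: no class column varies, so the model cannot fit;
  # the reference row is still pinned at 1 by construction
  draws <- tibble::tibble(rerun = 1:3, term = "mixed_sediment",
                          estimate = c(0.5, 0.1, -0.3))
  rss <- relative_selection_strength(
    structure(list(coefficients = draws, reference = "silt_mud_gravel"),
              class = "bs_rsf"))
  ref_row <- rss[rss$class == "silt_mud_gravel", ]
  expect_equal(ref_row$rss_median, 1)
  expect_equal(ref_row$rss_q25, 1)
  expect_equal(ref_row$rss_q75, 1)
})
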