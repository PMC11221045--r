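# Small in-code fixtures shared across test files.

# 2x2 raster: cell_size 10, origin (0,0), classes [[0,1],[2,3]] reading the
# matrix south-up (row 1 = south)
tiny_raster <- function() {
  bentho_raster(matrix(c(0L, 2L, 1L, 3L), nrow = 2), 0, 0, 10)
}

uniform_raster <- function(code = 4L, n = 50, cell = 1, origin = 0) {
  bentho_raster(matrix(code, n, n), origin, origin, cell)
}

# deterministic sync-fix tibble with chosen hpe/hpem values
sync_fix_tbl <- function(hpe, hpem = hpe, deployment = "dep1") {
  tibble::tibble(
    tag_id = "sync01", is_sync = TRUE, t = seq_along(hpe) * 180,
    x = 0, y = 0, hpe = hpe, hpem = hpem,
    deployment_id = deployment, release_t = 0
  )
}

animal_fix_tbl <- function(t, hpe = 1, tag = "a1", release = 0) {
  tibble::tibble(
    tag_id = tag, is_sync = FALSE, t = t, x = seq_along(t), y = 0,
    hpe = rep_len(hpe, length(t)), hpem = NA_real_,
    deployment_id = "dep1", release_t = release
  )
}

# one simulated individual, prepared up to classified steps
sim_steps <- function(raster, beta = c(mixed_sediment = 1),
                      n_steps = 500, seed = 1, shape = 1.5, scale = 3,
                      kappa = 1) {
  start <- c(mean(c(raster$origin_x, raster$origin_x +
                      raster$n_cols * raster$cell_size)),
             mean(c(raster$origin_y, raster$origin_y +
                      raster$n_rows * raster$cell_size)))
  tr <- simulate_track(raster, beta = beta, shape = shape, scale = scale,
                       kappa = kappa, start = start, n_steps = n_steps,
                       seed = seed)
  fx <- tibble::tibble(tag_id = "a1", t = tr$t, x = tr$x, y = tr$y)
  build_steps(resample_fixes(fx)) |>
    filter_steps() |>
    attach_covariates(raster)
}

# brute-force conditional log likelihood for a single covariate
clogit_loglik_1d <- function(beta, data) {
  sum(vapply(split(seq_len(nrow(data)), data$stratum), function(i) {
    eta <- beta * data$x[i]
    eta[data$case[i]] - log(sum(exp(eta)))
  }, numeric(1)))
}

# grid-search maximizer used as the independent oracle
clogit_grid_oracle <- function(data, lo = -5, hi = 5, step = 1e-3) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, clogit_loglik_1d, numeric(1), data = data)
  list(beta = grid[which.max(ll)], loglik = max(ll), grid = grid, ll = ll)
}

# random small stratified dataset with one covariate
random_strata_1d <- function(n_strata, n_controls = 3, beta = 0.8) {
  purrr::map_dfr(seq_len(n_strata), function(s) {
    x <- rnorm(n_controls + 1)
    pick <- sample(n_controls + 1, 1, prob = exp(beta * x))
    tibble::tibble(stratum = s, case = seq_len(n_controls + 1) == pick,
                   x = x)
  })
}
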