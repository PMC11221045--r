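#' Simulation configuration for the synthetic positioning system
#'
#' Bundles every knob of the synthetic world: the patchy benthoscape, the
#' step-selection process generating true tracks, and the observation model
#' emulating an acoustic positioning array (transmission schedule, detection
#' probability, positional error, and the unitless HPE quality score).
#'
#' Defaults reproduce the design conditions of the motivating array study:
#' transmissions every 120-240 s, a median positional error of about 2.4 m,
#' a five-class benthoscape plus a small nodata fraction, and 10-minute
#' analysis steps.
#'
#' @param n_rows,n_cols,cell_size Raster geometry (cells; metres per cell).
#' @param target_props Named target class proportions (must sum to 1);
#'   names are substrate levels.
#' @param patch_scale Patchiness length scale in metres (Gaussian smoothing
#'   bandwidth of the underlying random field).
#' @param beta Named true selection coefficients per substrate level;
#'   the reference class is fixed at 0.
#' @param shape,scale Gamma step-length kernel (scale in metres).
#' @param kappa von Mises turning-angle concentration (mean fixed at 0).
#' @param n_individuals,steps_per_individual Track dimensions.
#' @param step_interval Seconds between true positions (the analysis rate).
#' @param transmission_lo,transmission_hi Bounds (s) of the uniform
#'   transmission interval.
#' @param detection_prob Probability that a transmission yields a position.
#' @param sigma0 Baseline positional-error scale (m).
#' @param sigma_log_sd Log-normal spread of the per-fix error scale (the
#'   heavy-tailed mixture over fixes).
#' @param hpe_a,hpe_tau HPE coupling: `HPE = hpe_a * sigma_i * exp(eps)`,
#'   `eps ~ N(0, hpe_tau)`. HPE is a noisy, unitless proxy for error.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `bs_sim_config`.
#' @export
sim_config <- function(n_rows = 200, n_cols = 200, cell_size = 1,
                       target_props = c(coarse_sediment = 0.22,
                                        silt_mud_gravel = 0.12,
                                        mixed_sediment = 0.10,
                                        deep_silt_mud = 0.05,
                                        shallow_silt_mud = 0.49,
                                        nodata = 0.02),
                       patch_scale = 10,
                       beta = c(coarse_sediment = 0, silt_mud_gravel = 0,
                                mixed_sediment = 0, deep_silt_mud = 0,
                                shallow_silt_mud = 0, nodata = 0),
                       shape = 1.5, scale = 3, kappa = 1,
                       n_individuals = 5, steps_per_individual = 2000,
                       step_interval = 600,
                       transmission_lo = 120, transmission_hi = 240,
                       detection_prob = 0.85,
                       sigma0 = 2.04, sigma_log_sd = 0.6,
                       hpe_a = 10, hpe_tau = 0.35,
                       seed = 1L) {
  if (abs(sum(target_props) - 1) > 1e-8) {
    abort("`target_props` must sum to 1")
  }
  if (!all(names(target_props) %in% substrate_levels())) {
    abort("`target_props` names must be substrate levels")
  }
  if (sigma0 < 0) abort("`sigma0` must be >= 0")
  if (detection_prob < 0 || detection_prob > 1) {
    abort("`detection_prob` must be in [0, 1]")
  }
  if (!(transmission_lo > 0 && transmission_lo <= transmission_hi)) {
    abort("transmission interval bounds need 0 < lo <= hi")
  }
  structure(as.list(environment()), class = "bs_sim_config")
}

#' Generate a patchy categorical benthoscape
#'
#' Draws a Gaussian random field (white noise smoothed at `patch_scale`)
#' and thresholds it at the quantiles of the target class proportions, so
#' realized proportions track the targets while classes form spatial
#' patches. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A [bentho_raster()].
#' @export
generate_benthoscape <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "bs_sim_config"))
  seed <- seed %||% config$seed
  props <- config$target_props
  if (abs(sum(props) - 1) > 1e-8) abort("target proportions must sum to 1")
  nr <- config$n_rows; nc <- config$n_cols
  field <- with_seed(seed, {
    z <- matrix(rnorm(nr * nc), nr, nc)
    gaussian_blur(z, config$patch_scale / config$cell_size)
  })
  # quantile thresholding: class k occupies the band between cumulative
  # proportion cuts, so realized counts match targets up to ties
  cuts <- quantile(field, probs = cumsum(props)[-length(props)], type = 7)
  band <- findInterval(field, cuts, left.open = TRUE) + 1L
  codes <- substrate_code(names(props))
  m <- matrix(codes[band], nr, nc)
  bentho_raster(m, 0, 0, config$cell_size)
}

# separable Gaussian blur with replicated edges; sd in cells
gaussian_blur <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_cells))
  k <- dnorm(seq(-half, half), sd = sd_cells)
  k <- k / sum(k)
  blur1 <- function(a) {  # blur down columns, clamping indices at the edges
    n <- nrow(a)
    out <- matrix(0, n, ncol(a))
    for (j in seq_along(k)) {
      idx <- pmin(pmax(seq_len(n) + (j - 1L - half), 1L), n)
      out <- out + k[j] * a[idx, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' Simulate a track from a known step-selection process
#'
#' Runs the generative model of an integrated step-selection analysis
#' forward: at each step, `n_candidates` proposals are drawn from the
#' selection-free movement kernel (gamma step lengths; von Mises turning
#' angles about the previous bearing) and one is chosen with probability
#' proportional to `exp(beta[end class])`. Proposals leaving the raster are
#' redrawn up to `max_retries` rounds, after which the animal holds
#' position for that step.
#'
#' @param raster A [bentho_raster()].
#' @param beta Named selection coefficients per substrate level.
#' @param shape,scale,kappa Movement kernel parameters.
#' @param start Length-2 numeric `(x, y)` inside the raster.
#' @param n_steps Number of steps to simulate.
#' @param dt Seconds per step.
#' @param n_candidates Proposals per step (>= 10).
#' @param max_retries Redraw rounds before holding position.
#' @param seed Integer seed.
#' @return A tibble of class `bs_track` with columns `t`, `x`, `y`,
#'   `class` (substrate at the point); attributes `beta` and `kernel`.
#' @export
simulate_track <- function(raster, beta, shape, scale, kappa,
                           start, n_steps, dt = 600,
                           n_candidates = 20, max_retries = 50, seed = NULL) {
  stopifnot(inherits(raster, "bentho_raster"), length(start) == 2)
  if (n_candidates < 10) abort("`n_candidates` must be >= 10")
  if (!raster_contains(raster, start[1], start[2])) {
    abort("`start` is outside the raster")
  }
  beta_full <- setNames(rep(0, length(substrate_levels())), substrate_levels())
  if (length(beta) > 0) beta_full[names(beta)] <- beta

  xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
  xs[1] <- start[1]; ys[1] <- start[2]
  with_seed(seed, {
    bearing <- runif(1, -pi, pi)
    held <- 0L
    for (i in seq_len(n_steps)) {
      chosen <- FALSE
      for (retry in seq_len(max_retries)) {
        sl <- rgamma(n_candidates, shape = shape, scale = scale)
        ta <- rvonmises(n_candidates, kappa)
        br <- bearing + ta
        ex <- xs[i] + sl * cos(br)
        ey <- ys[i] + sl * sin(br)
        ok <- raster_contains(raster, ex, ey)
        if (any(ok)) {
          cls <- extract_class(raster, ex[ok], ey[ok])
          w <- exp(beta_full[as.character(cls)])
          pick <- sample.int(sum(ok), 1, prob = w)
          j <- which(ok)[pick]
          xs[i + 1] <- ex[j]; ys[i + 1] <- ey[j]
          bearing <- br[j]
          chosen <- TRUE
          break
        }
      }
      if (!chosen) {  # hold position; bearing unchanged
        xs[i + 1] <- xs[i]; ys[i + 1] <- ys[i]
        held <- held + 1L
      }
    }
    if (n_steps > 0 && held == n_steps) {
      abort("every step exhausted its proposal retries; use a larger raster or smaller steps")
    }
  })
  out <- tibble::tibble(
    t = seq(0, by = dt, length.out = n_steps + 1),
    x = xs, y = ys,
    class = extract_class(raster, xs, ys)
  )
  structure(out, class = c("bs_track", class(out)),
            beta = beta_full,
            kernel = list(shape = shape, scale = scale, kappa = kappa))
}

#' Observe a true track through the positioning system
#'
#' Emulates how an acoustic positioning array turns a continuous track into
#' a table of position fixes: transmissions at cumulative uniform
#' `(lo, hi)`-second intervals, linear interpolation of the true position,
#' Bernoulli detection, an isotropic bivariate normal positional error with
#' a heavy-tailed (log-normal) per-fix scale, and a unitless HPE score that
#' is a noisy but monotone-in-expectation proxy for the true error.
#'
#' @param track A [simulate_track()] result (or any tibble with `t,x,y`).
#' @param config A [sim_config()].
#' @param tag_id Tag identifier for the output rows.
#' @param deployment_id Deployment identifier.
#' @param seed Integer seed.
#' @return A tibble of position fixes: `tag_id`, `is_sync`, `t`, `x`, `y`,
#'   `hpe`, `hpem` (`NA` for animal tags), `deployment_id`, `release_t`,
#'   plus `true_x`, `true_y` kept for validation.
#' @export
observe_track <- function(track, config = sim_config(), tag_id = "tag1",
                          deployment_id = "dep1", seed = NULL) {
  stopifnot(is.data.frame(track), all(c("t", "x", "y") %in% names(track)))
  t0 <- min(track$t); t1 <- max(track$t)
  with_seed(seed %||% config$seed, {
    # transmission times: cumulative uniform intervals across the timeline
    n_max <- ceiling((t1 - t0) / config$transmission_lo) + 1
    gaps <- runif(n_max, config$transmission_lo, config$transmission_hi)
    tt <- t0 + cumsum(gaps)
    tt <- tt[tt <= t1]
    detected <- runif(length(tt)) < config$detection_prob
    tt <- tt[detected]
    tx <- approx(track$t, track$x, xout = tt)$y
    ty <- approx(track$t, track$y, xout = tt)$y
    n <- length(tt)
    sigma_i <- config$sigma0 * exp(rnorm(n, 0, config$sigma_log_sd))
    ox <- tx + rnorm(n, 0, sigma_i)
    oy <- ty + rnorm(n, 0, sigma_i)
    hpe <- config$hpe_a * sigma_i * exp(rnorm(n, 0, config$hpe_tau))
    tibble::tibble(
      tag_id = tag_id, is_sync = FALSE, t = tt, x = ox, y = oy,
      hpe = hpe, hpem = NA_real_, deployment_id = deployment_id,
      release_t = t0, true_x = tx, true_y = ty
    )
  })
}

#' Generate stationary sync-tag fixes with known error
#'
#' Places `n` stationary reference transmitters on a regular grid inside
#' the raster and observes them with the same error and HPE model as
#' animal tags. Because the true position is known, each fix carries
#' `hpem = |observed - true|` exactly — the measured error in metres used
#' to calibrate HPE cut-offs.
#'
#' @param raster A [bentho_raster()].
#' @param n Number of sync tags (>= 1).
#' @param config A [sim_config()].
#' @param n_fixes Fixes per tag.
#' @param deployment_id Deployment identifier.
#' @param seed Integer seed.
#' @return A fixes tibble (same schema as [observe_track()]) with
#'   `is_sync = TRUE` and `hpem` filled in.
#' @export
generate_sync_tags <- function(raster, n = 16, config = sim_config(),
                               n_fixes = 200, deployment_id = "dep1",
                               seed = NULL) {
  stopifnot(inherits(raster, "bentho_raster"))
  if (n < 1) abort("`n` must be >= 1")
  side <- ceiling(sqrt(n))
  gx <- raster$origin_x + (seq_len(side) - 0.5) / side *
    (raster_xmax(raster) - raster$origin_x)
  gy <- raster$origin_y + (seq_len(side) - 0.5) / side *
    (raster_ymax(raster) - raster$origin_y)
  pos <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  seeds <- derive_seeds(seed %||% config$seed, n)
  purrr::map_dfr(seq_len(n), function(i) {
    with_seed(seeds[[i]], {
      gaps <- runif(n_fixes, config$transmission_lo, config$transmission_hi)
      tt <- cumsum(gaps)
      m <- length(tt)
      sigma_i <- config$sigma0 * exp(rnorm(m, 0, config$sigma_log_sd))
      ox <- pos$x[i] + rnorm(m, 0, sigma_i)
      oy <- pos$y[i] + rnorm(m, 0, sigma_i)
      hpe <- config$hpe_a * sigma_i * exp(rnorm(m, 0, config$hpe_tau))
      tibble::tibble(
        tag_id = sprintf("sync%02d", i), is_sync = TRUE, t = tt,
        x = ox, y = oy, hpe = hpe,
        hpem = sqrt((ox - pos$x[i])^2 + (oy - pos$y[i])^2),
        deployment_id = deployment_id, release_t = 0,
        true_x = pos$x[i], true_y = pos$y[i]
      )
    })
  })
}

#' Read and write the position-fix CSV schema
#'
#' The on-disk schema uses ISO-8601 UTC timestamps and explicit column
#' names: `tag_id, is_sync, t_iso8601, x_m, y_m, hpe, hpem, deployment_id,
#' release_t_iso8601`. In memory, times are seconds since the epoch origin
#' used at write time.
#'
#' @param fixes A fixes tibble.
#' @param path CSV path.
#' @param epoch POSIXct origin for numeric `t` columns.
#' @return `read_positions_csv()` returns a fixes tibble.
#' @export
write_positions_csv <- function(fixes, path,
                                epoch = as.POSIXct("2020-01-01", tz = "UTC")) {
  iso <- function(t) format(epoch + t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  out <- data.frame(
    tag_id = fixes$tag_id, is_sync = fixes$is_sync,
    t_iso8601 = iso(fixes$t), x_m = fixes$x, y_m = fixes$y,
    hpe = fixes$hpe, hpem = fixes$hpem,
    deployment_id = fixes$deployment_id,
    release_t_iso8601 = iso(fixes$release_t)
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions_csv
#' @export
read_positions_csv <- function(path,
                               epoch = as.POSIXct("2020-01-01", tz = "UTC")) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  parse_t <- function(s) {
    t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
    if (anyNA(t)) abort("unparseable ISO-8601 timestamp in positions CSV")
    as.numeric(t) - as.numeric(epoch)
  }
  tibble::tibble(
    tag_id = d$tag_id, is_sync = as.logical(d$is_sync),
    t = parse_t(d$t_iso8601), x = d$x_m, y = d$y_m,
    hpe = d$hpe, hpem = d$hpem,
    deployment_id = d$deployment_id,
    release_t = parse_t(d$release_t_iso8601)
  )
}
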