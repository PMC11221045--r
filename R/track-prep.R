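#' Regularize fixes to a fixed sampling rate, split into bursts
#'
#' Greedy regularization: keep the first fix of a tag; from each kept fix,
#' keep the earliest subsequent fix whose time gap lies in
#' `[rate - tolerance, rate + tolerance]`. If no such fix exists before the
#' gap exceeds `rate + tolerance`, the burst is closed and a new one starts
#' at the first fix beyond the gap. Bursts with fewer than 2 kept fixes are
#' dropped.
#'
#' @param fixes Fixes tibble with `tag_id`, `t`, `x`, `y` (time-sorted per
#'   tag; unsorted input is an error, not silently reordered).
#' @param rate Target sampling interval in seconds (default 600 = 10 min).
#' @param tolerance Acceptance half-window in seconds (default 120).
#' @return A tibble of kept fixes with an added `burst_id` column
#'   (`"<tag>_<k>"`).
#' @export
resample_fixes <- function(fixes, rate = 600, tolerance = 120) {
  stopifnot(all(c("tag_id", "t", "x", "y") %in% names(fixes)))
  fixes |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::group_modify(function(d, key) {
      if (is.unsorted(d$t, strictly = FALSE)) {
        abort(paste0("fixes for tag ", key$tag_id, " are not time-sorted"))
      }
      n <- nrow(d)
      keep <- integer(0)
      burst <- integer(0)
      b <- 1L
      i <- 1L
      while (i <= n) {
        keep <- c(keep, i); burst <- c(burst, b)
        gap <- d$t - d$t[i]
        j <- which(gap >= rate - tolerance & gap <= rate + tolerance)
        j <- j[j > i]
        if (length(j) > 0) {
          i <- j[1]
        } else {
          # close the burst; restart at the first fix beyond the window
          nxt <- which(gap > rate + tolerance)
          nxt <- nxt[nxt > i]
          b <- b + 1L
          if (length(nxt) == 0) break
          i <- nxt[1]
        }
      }
      out <- d[keep, , drop = FALSE]
      out$burst_id <- paste0(key$tag_id, "_", burst)
      # drop singleton bursts
      out |>
        dplyr::group_by(.data$burst_id) |>
        dplyr::filter(dplyr::n() >= 2) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()
}

# wrap an angle into (-pi, pi]
wrap_angle <- function(a) {
  r <- (a + pi) %% (2 * pi) - pi
  r[r <= -pi] <- pi
  r
}

#' Build steps from regularized bursts
#'
#' One step per consecutive fix pair within a burst: step length `sl`
#' (Euclidean), `log_sl`, absolute bearing (`atan2(dy, dx)`,
#' counter-clockwise positive), and turning angle `ta` = change in bearing
#' wrapped into `(-pi, pi]`. The first step of each burst has no
#' predecessor, so its `ta` (and `cos_ta`) is `NA`.
#'
#' @param fixes Output of [resample_fixes()] (needs `burst_id`).
#' @return A steps tibble: `tag_id`, `burst_id`, `t_start`, `t_end`,
#'   `x_start`, `y_start`, `x_end`, `y_end`, `sl`, `log_sl`, `bearing`,
#'   `ta`, `cos_ta`.
#' @export
build_steps <- function(fixes) {
  stopifnot("burst_id" %in% names(fixes))
  fixes |>
    dplyr::group_by(.data$tag_id, .data$burst_id) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < 2) return(tibble::tibble())
      dx <- diff(d$x); dy <- diff(d$y)
      sl <- sqrt(dx^2 + dy^2)
      bearing <- atan2(dy, dx)
      ta <- c(NA_real_, wrap_angle(diff(bearing)))
      tibble::tibble(
        t_start = d$t[-n], t_end = d$t[-1],
        x_start = d$x[-n], y_start = d$y[-n],
        x_end = d$x[-1], y_end = d$y[-1],
        sl = sl, log_sl = log(sl), bearing = bearing,
        ta = ta, cos_ta = cos(ta)
      )
    }) |>
    dplyr::ungroup()
}

#' Apply the step filters
#'
#' Removes steps with non-finite `log_sl` (zero-length steps), and — when
#' `require_ta` — steps whose turning angle is not computable (the first
#' step of each burst). Removal counts per reason are attached as the
#' `"counts"` attribute.
#'
#' @param steps A steps tibble from [build_steps()].
#' @param require_ta Drop steps with missing turning angles (needed by any
#'   analysis using `cos_ta`).
#' @return The filtered steps tibble with attribute `"counts"`.
#' @export
filter_steps <- function(steps, require_ta = TRUE) {
  if (nrow(steps) == 0) {
    out <- steps
    attr(out, "counts") <- tibble::tibble(nonfinite_log_sl = 0L,
                                          missing_ta = 0L)
    return(out)
  }
  bad_sl <- !is.finite(steps$log_sl)
  bad_ta <- if (require_ta) is.na(steps$ta) else rep(FALSE, nrow(steps))
  out <- steps[!(bad_sl | bad_ta), , drop = FALSE]
  attr(out, "counts") <- tibble::tibble(
    nonfinite_log_sl = sum(bad_sl),
    missing_ta = sum(bad_ta & !bad_sl)
  )
  out
}

#' Attach substrate classes at step endpoints
#'
#' Samples the benthoscape at the start and end point of every step
#' (endpoint-only semantics: cells crossed mid-step are ignored). Endpoints
#' on nodata cells get the `nodata` level; endpoints outside the raster
#' extent are an error.
#'
#' @param steps A steps tibble.
#' @param raster A [bentho_raster()].
#' @return The steps tibble with `start_class` and `end_class` factors.
#' @export
attach_covariates <- function(steps, raster) {
  steps$start_class <- extract_class(raster, steps$x_start, steps$y_start)
  steps$end_class <- extract_class(raster, steps$x_end, steps$y_end)
  steps
}
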