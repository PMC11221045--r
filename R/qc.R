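#' Candidate HPE cut-off from sync-tag fixes
#'
#' For each receiver deployment (treated as its own dataset), finds the
#' lowest *observed* HPE value that retains at least `retain` of the
#' deployment's sync-tag positions. These candidates feed a human choice of
#' final cut-off; the package never picks the final value itself.
#'
#' @param sync_fixes Fixes tibble with `hpe` and `deployment_id`; sync
#'   fixes only (rows with `is_sync == FALSE` are rejected).
#' @param retain Target retention fraction (default 0.95).
#' @return A tibble with one row per deployment: `deployment_id`,
#'   `cutoff` (an observed HPE value), `retention` (achieved fraction,
#'   >= `retain`), `n_fixes`.
#' @export
candidate_cutoff <- function(sync_fixes, retain = 0.95) {
  if (nrow(sync_fixes) == 0) abort("no sync fixes supplied")
  if (any(!sync_fixes$is_sync)) {
    abort("candidate_cutoff expects sync-tag fixes only")
  }
  if (retain <= 0 || retain > 1) abort("`retain` must be in (0, 1]")
  sync_fixes |>
    dplyr::group_by(.data$deployment_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 20) {
        abort(paste0("deployment ", key$deployment_id,
                     " has fewer than 20 sync fixes"))
      }
      h <- sort(d$hpe)
      n <- length(h)
      # smallest observed h* with fraction(hpe <= h*) >= retain
      k <- ceiling(retain * n)
      cutoff <- h[k]
      tibble::tibble(cutoff = cutoff,
                     retention = mean(d$hpe <= cutoff),
                     n_fixes = n)
    }) |>
    dplyr::ungroup()
}

#' HPEm percentile report at a cut-off
#'
#' Filters sync fixes at a candidate HPE cut-off and reports the measured
#' error (HPEm) percentiles of the surviving positions: the median, 90th
#' and 95th percentiles, by linear interpolation between order statistics.
#'
#' @param sync_fixes Sync fixes with `hpe` and `hpem`.
#' @param cutoff HPE cut-off (> 0).
#' @param comparator `"<="` (default, matching the retention definition) or
#'   `"<"`.
#' @return A one-row tibble: `cutoff`, `n_pass`, `retention`,
#'   `hpem_median`, `hpem_p90`, `hpem_p95`.
#' @export
cutoff_report <- function(sync_fixes, cutoff, comparator = c("<=", "<")) {
  if (!is.numeric(cutoff) || cutoff <= 0) abort("`cutoff` must be > 0")
  comparator <- match.arg(comparator)
  pass <- if (comparator == "<=") sync_fixes$hpe <= cutoff else
    sync_fixes$hpe < cutoff
  if (!any(pass)) abort("no sync fixes pass the cut-off")
  hm <- sync_fixes$hpem[pass]
  if (anyNA(hm)) abort("sync fixes must carry hpem")
  qs <- quantile(hm, c(0.5, 0.9, 0.95), type = 7, names = FALSE)
  tibble::tibble(cutoff = cutoff, n_pass = sum(pass),
                 retention = mean(pass),
                 hpem_median = qs[1], hpem_p90 = qs[2], hpem_p95 = qs[3])
}

#' Filter animal positions at the final cut-off and post-release window
#'
#' Applies the final filtering protocol to animal fixes: keep a fix only if
#' its HPE is *strictly below* the chosen cut-off and its timestamp is at
#' least `post_release_hours` after the tag's release. Every animal tag
#' must have a release time; unknown tags are an error, never silently
#' kept.
#'
#' @param fixes Fixes tibble (animal rows are filtered; sync rows are
#'   dropped from the output).
#' @param cutoff Final HPE cut-off (strict `<`).
#' @param releases Optional named vector/list of release times per tag id;
#'   defaults to the `release_t` column.
#' @param post_release_hours Hours after release to discard (default 48).
#' @return The filtered fixes tibble, with an attribute `"counts"`: a
#'   per-tag tibble of rows before/after and removals by reason.
#' @export
filter_positions <- function(fixes, cutoff = 25, releases = NULL,
                             post_release_hours = 48) {
  animal <- fixes[!fixes$is_sync, , drop = FALSE]
  if (is.null(releases)) {
    if (!"release_t" %in% names(animal) || anyNA(animal$release_t)) {
      abort("no release times: supply `releases` or a complete `release_t` column")
    }
    rel <- animal$release_t
  } else {
    releases <- unlist(releases)
    missing <- setdiff(unique(animal$tag_id), names(releases))
    if (length(missing) > 0) {
      abort(paste0("no release time for tag(s): ",
                   paste(missing, collapse = ", ")))
    }
    rel <- unname(releases[animal$tag_id])
  }
  ok_hpe <- animal$hpe < cutoff
  ok_time <- animal$t >= rel + post_release_hours * 3600
  keep <- ok_hpe & ok_time
  counts <- tibble::tibble(tag_id = animal$tag_id,
                           ok_hpe = ok_hpe, ok_time = ok_time) |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(
      n_before = dplyr::n(),
      n_after = sum(.data$ok_hpe & .data$ok_time),
      removed_hpe = sum(!.data$ok_hpe),
      removed_post_release = sum(!.data$ok_time),
      .groups = "drop"
    )
  out <- animal[keep, , drop = FALSE]
  attr(out, "counts") <- counts
  out
}
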