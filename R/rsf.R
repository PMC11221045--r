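#' Draw pseudo-absences within each individual's availability domain
#'
#' For each tag, samples `ratio` pseudo-absence points per presence,
#' uniformly inside the minimum convex polygon (MCP) of that individual's
#' presences, and attaches the substrate class of every point from the
#' raster. Pseudo-absences landing on nodata cells keep `nodata` as their
#' class level.
#'
#' @param presences Tibble with `tag_id`, `x`, `y` (one row per presence).
#' @param raster A [bentho_raster()].
#' @param ratio Pseudo-absences per presence (default 10).
#' @param seed Integer seed.
#' @return A use-available tibble: `tag_id`, `x`, `y`, `class`, `case`
#'   (`TRUE` = presence).
#' @export
draw_pseudo_absences <- function(presences, raster, ratio = 10, seed = NULL) {
  stopifnot(all(c("tag_id", "x", "y") %in% names(presences)))
  tags <- unique(presences$tag_id)
  seeds <- derive_seeds(seed, length(tags))
  purrr::map_dfr(seq_along(tags), function(i) {
    d <- presences[presences$tag_id == tags[i], , drop = FALSE]
    if (nrow(d) < 5) {
      abort(paste0("tag ", tags[i], " has fewer than 5 presences"))
    }
    hull_idx <- grDevices::chull(d$x, d$y)
    hx <- d$x[hull_idx]; hy <- d$y[hull_idx]
    if (length(hull_idx) < 3 ||
        abs(polygon_area(hx, hy)) < 1e-12 * max(1, max(abs(c(hx, hy))))^2) {
      abort(paste0("tag ", tags[i],
                   ": presences are collinear (zero-area MCP)"))
    }
    mcp <- bs_polygon(hx, hy)
    n_abs <- ratio * nrow(d)
    pts <- with_seed(seeds[[i]], sample_in_polygon(mcp, n_abs))
    dplyr::bind_rows(
      tibble::tibble(tag_id = tags[i], x = d$x, y = d$y,
                     class = extract_class(raster, d$x, d$y), case = TRUE),
      tibble::tibble(tag_id = tags[i], x = pts$x, y = pts$y,
                     class = extract_class(raster, pts$x, pts$y),
                     case = FALSE)
    )
  })
}

# uniform points inside a polygon by bounding-box rejection
sample_in_polygon <- function(poly, n, max_rounds = 1000) {
  bb <- apply(unclass(poly), 2, range)
  xs <- numeric(0); ys <- numeric(0)
  # expected acceptance = area / bbox area; draw in batches
  batch <- max(100L, 2L * n)
  for (round in seq_len(max_rounds)) {
    cx <- runif(batch, bb[1, 1], bb[2, 1])
    cy <- runif(batch, bb[1, 2], bb[2, 2])
    ok <- points_in_polygon(poly, cx, cy)
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
    if (length(xs) >= n) break
  }
  if (length(xs) < n) abort("polygon sampling failed (degenerate polygon?)")
  tibble::tibble(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Subsample-refit resource selection analysis
#'
#' The RSF scheme of the pipeline: the use-available logistic model
#' (presence ~ substrate class, individual as a random intercept) is refit
#' `reruns` times, each time on a random subset of `per_individual`
#' presences and `per_individual` pseudo-absences per individual (sampled
#' without replacement). The spread of the rerun coefficients, not a
#' single fit's standard errors, carries the uncertainty — the repeated
#' subsampling is the scheme's mitigation of spatial autocorrelation
#' between consecutive positions.
#'
#' The default `scheme = "equal"` reads "100 presence and pseudo-absence
#' points" as 100 of each; `scheme = "ratio"` instead pairs each of the
#' `per_individual` presences with `ratio` times as many pseudo-absences.
#' In the use-available logistic framework the use:available ratio shifts
#' only the intercept, so class coefficients agree between schemes.
#'
#' @param data A use-available tibble from [draw_pseudo_absences()].
#' @param reruns Number of subsample refits (default 100).
#' @param per_individual Presences (and pseudo-absences) per individual
#'   per rerun (default 100).
#' @param scheme `"equal"` or `"ratio"` (see Details).
#' @param ratio Pseudo-absence multiplier for `scheme = "ratio"`.
#' @param reference Reference substrate level.
#' @param seed Integer seed.
#' @return An object of class `bs_rsf`: `coefficients` tibble
#'   (rerun x term estimate), `excluded` tags, `reference`, `reruns`.
#' @export
rsf_resample_fit <- function(data, reruns = 100, per_individual = 100,
                             scheme = c("equal", "ratio"), ratio = 10,
                             reference = substrate_reference(),
                             seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("tag_id", "class", "case") %in% names(data)))
  n_abs_needed <- if (scheme == "equal") per_individual else
    per_individual * ratio
  ok_tab <- data |>
    dplyr::count(.data$tag_id, .data$case) |>
    tidyr::pivot_wider(names_from = "case", values_from = "n",
                       values_fill = 0L)
  usable <- ok_tab$tag_id[ok_tab$`TRUE` >= per_individual &
                            ok_tab$`FALSE` >= n_abs_needed]
  excluded <- setdiff(ok_tab$tag_id, usable)
  if (length(excluded) > 0) {
    warn(paste0("excluding individual(s) with insufficient points: ",
                paste(excluded, collapse = ", ")))
  }
  if (length(usable) < 2) {
    abort("fewer than 2 usable individuals for the random-intercept RSF")
  }
  d <- data[data$tag_id %in% usable, , drop = FALSE]
  d$class <- stats::relevel(factor(d$class, levels = substrate_levels()),
                            ref = reference)
  d$class <- droplevels(d$class)
  if (nlevels(d$class) < 2) {
    abort("fewer than 2 substrate classes present; selection is undefined")
  }
  pres_idx <- split(which(d$case), d$tag_id[d$case])
  abs_idx <- split(which(!d$case), d$tag_id[!d$case])
  seeds <- derive_seeds(seed, reruns)
  failed <- 0L
  coefs <- purrr::map_dfr(seq_len(reruns), function(r) {
    rows <- with_seed(seeds[[r]], {
      unlist(lapply(usable, function(tg) {
        c(sample(pres_idx[[tg]], per_individual),
          sample(abs_idx[[tg]], n_abs_needed))
      }))
    })
    dd <- d[rows, c("tag_id", "case", "class")]
    # a class represented only among presences or only among absences in
    # this subsample is quasi-separated (its coefficient sits at +-Inf);
    # such levels contribute no draw this rerun — the "-" cells of a
    # sparse dataset — and their rows are set aside before fitting
    tab <- table(dd$class, dd$case)
    sep_lv <- rownames(tab)[(tab[, 1] == 0 | tab[, 2] == 0) &
                              rowSums(tab) > 0]
    sep_lv <- setdiff(sep_lv, reference)
    if (length(sep_lv) > 0) {
      dd <- dd[!dd$class %in% sep_lv, , drop = FALSE]
      dd$class <- droplevels(dd$class)
    }
    fit <- tryCatch({
      if (!reference %in% dd$class || nlevels(dd$class) < 2 ||
          length(unique(dd$tag_id)) < 2) NULL else
        fit_logistic_re(dd, response = "case", group = "tag_id",
                        covariates = "class")
    }, error = function(e) NULL)
    if (is.null(fit)) { failed <<- failed + 1L; return(tibble::tibble()) }
    est <- fit$coefficients
    cls_terms <- grep("^class", names(est), value = TRUE)
    tibble::tibble(rerun = r,
                   term = sub("^class", "", cls_terms),
                   estimate = unname(est[cls_terms]))
  })
  if (failed > 0) {
    warn(sprintf("%d of %d reruns failed to fit (separation) and were skipped",
                 failed, reruns))
  }
  if (failed > reruns / 2) {
    abort("more than half of the reruns failed to fit; data too sparse")
  }
  structure(list(coefficients = coefs, excluded = excluded,
                 reference = reference, reruns = reruns,
                 n_failed = failed,
                 per_individual = per_individual, scheme = scheme),
            class = "bs_rsf")
}

#' @export
print.bs_rsf <- function(x, ...) {
  cat("<bs_rsf> ", x$reruns, " subsample refits, reference ",
      x$reference, "\n", sep = "")
  print(relative_selection_strength(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bs_rsf <- function(x, ...) x$coefficients

#' Relative selection strength from rerun coefficients
#'
#' Exponentiates each rerun's class coefficients into relative selection
#' strengths (RSS) against the reference substrate and summarizes the
#' distribution per class: median, interquartile range, and a flag for
#' classes whose IQR spans 1 — coefficient draws on both sides of zero,
#' read as no clear selection.
#'
#' @param x A [rsf_resample_fit()] result, or a tibble with `term` and
#'   `estimate` columns of coefficient draws.
#' @return A tibble of class `bs_rss`: `class`, `rss_median`, `rss_q25`,
#'   `rss_q75`, `n_draws`, `no_clear_selection`; the reference class is
#'   included with RSS identically 1.
#' @export
relative_selection_strength <- function(x) {
  coefs <- if (inherits(x, "bs_rsf")) x$coefficients else x
  reference <- if (inherits(x, "bs_rsf")) x$reference else NA_character_
  if (nrow(coefs) == 0) abort("no coefficient draws")
  out <- coefs |>
    dplyr::group_by(class = .data$term) |>
    dplyr::summarise(
      rss_median = exp(median(.data$estimate)),
      rss_q25 = exp(quantile(.data$estimate, 0.25, names = FALSE)),
      rss_q75 = exp(quantile(.data$estimate, 0.75, names = FALSE)),
      n_draws = dplyr::n(),
      no_clear_selection = rss_q25 < 1 & rss_q75 > 1,
      .groups = "drop"
    )
  if (!is.na(reference)) {
    out <- dplyr::bind_rows(
      tibble::tibble(class = reference, rss_median = 1, rss_q25 = 1,
                     rss_q75 = 1, n_draws = max(out$n_draws),
                     no_clear_selection = FALSE),
      out
    )
  }
  class(out) <- c("bs_rss", class(out))
  out
}
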