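#' Fit the tentative movement kernel of one individual
#'
#' Gamma step lengths and von Mises (mean 0) turning angles fitted by
#' maximum likelihood to an individual's observed steps. This
#' "tentative" kernel generates the random steps; the conditional-logistic
#' movement coefficients later correct it.
#'
#' @param steps A steps tibble (one individual) with `sl` and `ta`.
#' @return A list of class `bs_kernel`: `gamma` ([fit_gamma()]) and
#'   `vonmises` ([fit_vonmises()]).
#' @export
fit_tentative_kernel <- function(steps) {
  sl <- steps$sl[is.finite(steps$log_sl)]
  ta <- steps$ta[!is.na(steps$ta)]
  structure(list(gamma = fit_gamma(sl), vonmises = fit_vonmises(ta)),
            class = "bs_kernel")
}

#' @export
print.bs_kernel <- function(x, ...) {
  cat("<bs_kernel> gamma(shape ", format(x$gamma$shape, digits = 4),
      ", scale ", format(x$gamma$scale, digits = 4),
      "), von Mises(kappa ", format(x$vonmises$kappa, digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' Generate random steps and assemble strata
#'
#' For every observed step with a computable turning angle, draws `n`
#' random alternatives from the tentative kernel — step length from the
#' fitted gamma, turning angle from the fitted von Mises about the
#' previous bearing — sharing the observed step's start point. End classes
#' are attached from the raster; ends on nodata cells keep the `nodata`
#' level, while ends beyond the raster extent are resampled (up to
#' `max_retries` rounds, after which the stratum is dropped with a
#' warning).
#'
#' @param steps One individual's steps tibble (with `bearing`, `ta`,
#'   `start_class`; see [build_steps()] and [attach_covariates()]).
#' @param kernel A [fit_tentative_kernel()] result.
#' @param n Random steps per stratum (default 100).
#' @param raster A [bentho_raster()].
#' @param max_retries Redraw rounds for out-of-extent ends.
#' @param seed Integer seed.
#' @return A strata tibble of class `bs_strata`: each stratum holds 1
#'   observed row (`case = TRUE`) and `n` random rows sharing `stratum`,
#'   `tag_id`, `start_class`; columns `sl`, `log_sl`, `ta`, `cos_ta`,
#'   `end_class`.
#' @export
draw_random_steps <- function(steps, kernel, n = 100, raster,
                              max_retries = 100, seed = NULL) {
  if (!inherits(kernel, "bs_kernel")) {
    abort("`kernel` must be a fitted bs_kernel (see fit_tentative_kernel)")
  }
  obs <- steps[!is.na(steps$ta) & is.finite(steps$log_sl), , drop = FALSE]
  if (nrow(obs) == 0) abort("no steps with computable turning angles")
  shape <- kernel$gamma$shape; scale <- kernel$gamma$scale
  kappa <- kernel$vonmises$kappa
  n_obs <- nrow(obs)
  prev_bearing <- wrap_angle(obs$bearing - obs$ta)
  dropped <- 0L
  out <- with_seed(seed, {
    pieces <- vector("list", n_obs)
    for (i in seq_len(n_obs)) {
      need <- n
      sl_acc <- numeric(0); ta_acc <- numeric(0)
      ex_acc <- numeric(0); ey_acc <- numeric(0)
      for (retry in seq_len(max_retries)) {
        sl <- rgamma(need, shape = shape, scale = scale)
        ta <- rvonmises(need, kappa)
        br <- prev_bearing[i] + ta
        ex <- obs$x_start[i] + sl * cos(br)
        ey <- obs$y_start[i] + sl * sin(br)
        ok <- raster_contains(raster, ex, ey)
        sl_acc <- c(sl_acc, sl[ok]); ta_acc <- c(ta_acc, ta[ok])
        ex_acc <- c(ex_acc, ex[ok]); ey_acc <- c(ey_acc, ey[ok])
        need <- n - length(sl_acc)
        if (need == 0) break
      }
      if (need > 0) { dropped <- dropped + 1L; next }
      end_class <- extract_class(raster, ex_acc, ey_acc)
      pieces[[i]] <- tibble::tibble(
        stratum = paste0(obs$tag_id[i], "_", i),
        tag_id = obs$tag_id[i],
        case = c(TRUE, rep(FALSE, n)),
        sl = c(obs$sl[i], sl_acc),
        log_sl = log(c(obs$sl[i], sl_acc)),
        ta = c(obs$ta[i], ta_acc),
        cos_ta = cos(c(obs$ta[i], ta_acc)),
        start_class = obs$start_class[i],
        end_class = factor(
          c(as.character(obs$end_class[i]), as.character(end_class)),
          levels = substrate_levels())
      )
    }
    dplyr::bind_rows(pieces)
  })
  if (dropped > 0) {
    warn(sprintf("%d stratum/strata dropped: random-step retries exhausted",
                 dropped))
  }
  class(out) <- c("bs_strata", class(out))
  out
}

#' Build the conditional-logistic design for the iSSF
#'
#' Expands strata into the model's design columns: reference-coded
#' end-class dummies (habitat selection), `log_sl` and `cos_ta` (movement),
#' and start-class interactions with each of `log_sl` and `cos_ta`
#' (movement modified by the substrate the step departs from). Start-class
#' *main* effects are stratum-constant, hence inestimable under the
#' conditional likelihood, and are intentionally absent. End-class levels
#' that never vary within any stratum are flagged as inestimable.
#'
#' @param strata A [draw_random_steps()] result.
#' @param reference Reference substrate level.
#' @param min_start_strata,min_end_cases Identifiability floors: start
#'   classes occurring in fewer strata, or end classes reached by fewer
#'   observed steps, are flagged inestimable and excluded — a level
#'   supported by a handful of observed steps cannot carry a stable
#'   coefficient, and a stratum bootstrap over it degenerates.
#' @return A tibble with `case`, `stratum` and numeric design columns;
#'   attribute `"inestimable"` lists flagged class levels.
#' @export
build_issf_design <- function(strata, reference = substrate_reference(),
                              min_start_strata = 5, min_end_cases = 5) {
  stopifnot(all(c("case", "stratum", "end_class", "start_class",
                  "log_sl", "cos_ta") %in% names(strata)))
  end_f <- droplevels(factor(strata$end_class))
  start_f <- droplevels(factor(strata$start_class))
  end_levels <- setdiff(levels(end_f), reference)
  start_levels <- setdiff(levels(start_f), reference)
  # an end class never reached by any observed step (or only ever reached
  # by observed steps) has its coefficient at +-infinity under the
  # conditional likelihood; such levels are inestimable — the "-" cells of
  # a per-individual results table — and are excluded with a flag
  inest <- character(0)
  for (lv in end_levels) {
    n_case <- sum(strata$case & end_f == lv)
    n_ctrl <- sum(!strata$case & end_f == lv)
    if ((n_case < min_end_cases && n_case + n_ctrl > 0) || n_ctrl == 0) {
      inest <- c(inest, lv)
    }
  }
  end_levels <- setdiff(end_levels, inest)
  # start-class interactions need enough strata starting on the level
  strata_start <- strata$start_class[strata$case]
  start_counts <- table(factor(strata_start, levels = start_levels))
  rare_start <- names(start_counts)[start_counts < min_start_strata]
  if (length(rare_start) > 0) inest <- c(inest, rare_start)
  start_levels <- setdiff(start_levels, rare_start)
  out <- tibble::tibble(case = strata$case, stratum = strata$stratum)
  for (lv in end_levels) {
    out[[paste0("end_", lv)]] <- as.numeric(end_f == lv)
  }
  out$log_sl <- strata$log_sl
  out$cos_ta <- strata$cos_ta
  for (lv in start_levels) {
    ind <- as.numeric(start_f == lv)
    out[[paste0("start_", lv, ":log_sl")]] <- ind * strata$log_sl
    out[[paste0("start_", lv, ":cos_ta")]] <- ind * strata$cos_ta
  }
  # end-class columns with no within-stratum variation anywhere
  sid <- factor(strata$stratum)
  for (lv in end_levels) {
    v <- out[[paste0("end_", lv)]]
    rng <- tapply(v, sid, function(z) max(z) - min(z))
    if (all(rng == 0)) inest <- c(inest, lv)
  }
  attr(out, "inestimable") <- inest
  out
}

#' Fit the integrated step-selection function of one individual
#'
#' Point fit by stratified conditional logistic regression on the design
#' of [build_issf_design()], then a stratum bootstrap for the replicate
#' mean and SD of every term. Individuals with fewer than `min_strata`
#' usable strata are refused, mirroring the practice of excluding
#' individuals with too few positions to support the model.
#'
#' @param strata A [draw_random_steps()] result.
#' @param B Bootstrap replicates (default 1000).
#' @param min_strata Minimum usable strata (default 20).
#' @param reference Reference substrate level.
#' @param seed Integer seed.
#' @param conf_level Level for both interval flavours.
#' @return An object of class `bs_issf`: `estimates` tibble (term,
#'   estimate, std.error, boot_mean, boot_sd, Wald and percentile CIs),
#'   `point` (`bs_clogit`), `boot` (`bs_clogit_boot`), `reference`,
#'   `n_strata`.
#' @export
fit_issf <- function(strata, B = 1000, min_strata = 20,
                     reference = substrate_reference(), seed = NULL,
                     conf_level = 0.95) {
  design <- build_issf_design(strata, reference = reference)
  n_strata <- length(unique(design$stratum))
  if (n_strata < min_strata) {
    abort(sprintf("only %d strata; at least %d required for an iSSF fit",
                  n_strata, min_strata))
  }
  boot <- bootstrap_clogit(design, case = "case", stratum = "stratum",
                           B = B, seed = seed, keep_draws = TRUE)
  point <- boot$point
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  qs <- apply(boot$draws, 2, quantile,
              probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
              names = FALSE)
  estimates <- tibble::tibble(
    term = point$terms,
    estimate = unname(point$coefficients),
    std.error = unname(point$se),
    boot_mean = boot$summary$boot_mean,
    boot_sd = boot$summary$boot_sd,
    conf.low.wald = unname(point$coefficients) - z * unname(point$se),
    conf.high.wald = unname(point$coefficients) + z * unname(point$se),
    conf.low.boot = qs[1, ],
    conf.high.boot = qs[2, ]
  )
  structure(list(estimates = estimates, point = point, boot = boot,
                 reference = reference, n_strata = n_strata,
                 inestimable = attr(design, "inestimable")),
            class = "bs_issf")
}

#' @export
print.bs_issf <- function(x, ...) {
  cat("<bs_issf> ", x$n_strata, " strata, reference ", x$reference,
      "\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bs_issf <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.bs_issf <- function(x, ...) {
  tibble::tibble(n.strata = x$n_strata,
                 logLik = x$point$loglik,
                 boot.converged = x$boot$n_converged,
                 B = x$boot$B)
}

#' Update the tentative kernel with fitted movement coefficients
#'
#' Corrects the selection-free kernel per start-class: on the reference
#' substrate the gamma shape gains the `log_sl` coefficient and the von
#' Mises concentration gains the `cos_ta` coefficient; on any other
#' substrate the respective start-class interaction coefficient is added
#' on top. A corrected shape that is not positive (or a negative
#' concentration) is flagged invalid rather than silently clipped.
#'
#' @param kernel A [fit_tentative_kernel()] result.
#' @param fit A [fit_issf()] result (or its `estimates` tibble); the
#'   bootstrap mean is used when present, else the point estimate.
#' @param use Which estimate column to apply: `"boot_mean"` or
#'   `"estimate"`.
#' @return A tibble of class `bs_updated_kernel`: `start_class`, `shape`,
#'   `kappa`, `valid`.
#' @export
update_kernel <- function(kernel, fit, use = c("boot_mean", "estimate")) {
  use <- match.arg(use)
  est <- if (inherits(fit, "bs_issf")) fit$estimates else fit
  if (!use %in% names(est)) use <- "estimate"
  val <- setNames(est[[use]], est$term)
  reference <- if (inherits(fit, "bs_issf")) fit$reference else
    substrate_reference()
  b_logsl <- unname(val["log_sl"] %||% 0)
  b_costa <- unname(val["cos_ta"] %||% 0)
  if (is.na(b_logsl)) b_logsl <- 0
  if (is.na(b_costa)) b_costa <- 0
  start_levels <- unique(sub(":(log_sl|cos_ta)$", "",
                             sub("^start_", "",
                                 grep("^start_", est$term, value = TRUE))))
  classes <- c(reference, start_levels)
  shape <- kappa <- numeric(length(classes))
  for (i in seq_along(classes)) {
    add_sl <- if (i == 1) 0 else
      unname(val[paste0("start_", classes[i], ":log_sl")] %||% 0)
    add_ct <- if (i == 1) 0 else
      unname(val[paste0("start_", classes[i], ":cos_ta")] %||% 0)
    if (is.na(add_sl)) add_sl <- 0
    if (is.na(add_ct)) add_ct <- 0
    shape[i] <- kernel$gamma$shape + b_logsl + add_sl
    kappa[i] <- kernel$vonmises$kappa + b_costa + add_ct
  }
  out <- tibble::tibble(
    start_class = classes,
    shape = shape,
    scale = kernel$gamma$scale,
    kappa = kappa,
    valid = shape > 0 & kappa >= 0
  )
  class(out) <- c("bs_updated_kernel", class(out))
  out
}

#' Behavioural reading of iSSF coefficients
#'
#' Translates coefficient signs into the standard behavioural labels: a
#' negative start-class x `cos_ta` interaction means lower directionality
#' (more turning) on that substrate than on the reference; a negative
#' start-class x `log_sl` interaction means shorter steps (more
#' residency); an end-class relative selection strength above 1 means the
#' substrate is selected over the reference when ending a step. Labels are
#' a pure function of signs.
#'
#' @param fit A [fit_issf()] result or its `estimates` tibble.
#' @param use Estimate column to interpret.
#' @return A tibble: `term`, `value`, `aspect` (`selection`,
#'   `directionality`, `step_length`), `label`.
#' @export
interpret_estimates <- function(fit, use = c("boot_mean", "estimate")) {
  use <- match.arg(use)
  est <- if (inherits(fit, "bs_issf")) fit$estimates else fit
  if (!use %in% names(est)) use <- "estimate"
  purrr::map_dfr(seq_len(nrow(est)), function(i) {
    term <- est$term[i]
    v <- est[[use]][i]
    if (grepl("^end_", term)) {
      cls <- sub("^end_", "", term)
      lab <- if (v > 0) paste0("selected over reference (", cls, ")")
      else if (v < 0) paste0("avoided relative to reference (", cls, ")")
      else "no difference from reference"
      asp <- "selection"
    } else if (grepl(":cos_ta$", term)) {
      cls <- sub(":cos_ta$", "", sub("^start_", "", term))
      lab <- if (v < 0) paste0("lower directionality / more turning on ", cls)
      else if (v > 0) paste0("higher directionality on ", cls)
      else "no difference from reference"
      asp <- "directionality"
    } else if (grepl(":log_sl$", term)) {
      cls <- sub(":log_sl$", "", sub("^start_", "", term))
      lab <- if (v < 0) paste0("shorter steps / more resident on ", cls)
      else if (v > 0) paste0("longer steps / more exploratory on ", cls)
      else "no difference from reference"
      asp <- "step_length"
    } else {
      lab <- if (v == 0) "no difference from reference" else
        paste0(term, if (v > 0) " increases" else " decreases",
               " selection weight")
      asp <- "movement"
    }
    tibble::tibble(term = term, value = v, aspect = asp, label = lab)
  })
}
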