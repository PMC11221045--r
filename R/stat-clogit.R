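#' Stratified conditional logistic regression
#'
#' Maximizes the conditional (multinomial-choice) log likelihood
#' `sum_s w_s [eta_case - log sum_j exp(eta_j)]` over strata each holding
#' exactly one case (the observed step) and `m` controls (random steps),
#' by Newton-Raphson with analytic gradient and Hessian and step halving.
#' Covariates constant within every stratum carry no information under the
#' conditional likelihood and are dropped with a report. Coefficients
#' wandering past `beta_guard` trigger a separation error naming the term,
#' rather than silently diverging.
#'
#' Optional per-stratum weights support the stratum bootstrap without
#' materializing resampled rows: a replicate is just the multinomial count
#' of each stratum.
#'
#' @param data A data frame with a logical/0-1 case column, a stratum id
#'   column, and numeric covariate columns (all other numeric columns are
#'   used as covariates).
#' @param case,stratum Column names (strings) of the case flag and stratum
#'   id. Defaults `"case"` and `"stratum"`.
#' @param stratum_weights Optional non-negative weights, one per stratum
#'   in order of first appearance (default all 1).
#' @param init Optional named starting values (used to warm-start
#'   bootstrap refits).
#' @param beta_guard Separation guard on `|beta|`.
#' @param max_iter,tol Newton controls.
#' @return An object of class `bs_clogit`: coefficients, `se`, `vcov`,
#'   `loglik`, `null_loglik`, `converged`, `iterations`, `n_strata`,
#'   `dropped` (stratum-constant terms).
#' @export
fit_clogit <- function(data, case = "case", stratum = "stratum",
                       stratum_weights = NULL, init = NULL,
                       beta_guard = 15, max_iter = 50, tol = 1e-9) {
  prep <- clogit_prepare(data, case, stratum)
  clogit_fit_prepared(prep, stratum_weights = stratum_weights, init = init,
                      beta_guard = beta_guard, max_iter = max_iter,
                      tol = tol)
}

# one-time design preparation shared by the point fit and every bootstrap
# replicate
clogit_prepare <- function(data, case, stratum) {
  y <- data[[case]]
  if (is.logical(y)) y <- as.numeric(y)
  s <- data[[stratum]]
  covs <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                  c(case, stratum))
  if (length(covs) == 0) abort("no numeric covariate columns found")
  X <- as.matrix(data[covs])
  sid <- as.integer(factor(s, levels = unique(s)))
  n_strata <- max(sid)
  counts <- tabulate(sid)
  case_per <- rowsum(y, sid)
  if (any(case_per != 1)) {
    abort("every stratum must contain exactly one case")
  }
  # drop covariates with no within-stratum variation anywhere
  smean <- rowsum(X, sid) / counts
  dev <- X - smean[sid, , drop = FALSE]
  keep <- apply(abs(dev), 2, max) > 1e-10
  dropped <- covs[!keep]
  if (!any(keep)) abort("no covariate varies within any stratum")
  # sparse stratum indicator: G %*% v sums v within strata (precomputed
  # once; the bootstrap reuses it for every replicate)
  G <- Matrix::sparseMatrix(i = sid, j = seq_along(sid), x = 1,
                            dims = c(n_strata, length(sid)))
  list(X = X[, keep, drop = FALSE], y = y, sid = sid, G = G,
       n_strata = n_strata, counts = counts,
       covs = covs[keep], dropped = dropped)
}

clogit_fit_prepared <- function(prep, stratum_weights = NULL, init = NULL,
                                beta_guard = 15, max_iter = 50, tol = 1e-9) {
  X <- prep$X; y <- prep$y; sid <- prep$sid
  n_strata <- prep$n_strata; counts <- prep$counts
  covs <- prep$covs; dropped <- prep$dropped
  sw <- stratum_weights %||% rep(1, n_strata)
  if (length(sw) != n_strata || any(sw < 0)) {
    abort("`stratum_weights` must be non-negative, one per stratum")
  }
  w_row <- sw[sid]
  p <- ncol(X)

  beta <- rep(0, p)
  if (!is.null(init)) {
    i <- match(covs, names(init))
    beta[!is.na(i)] <- init[i[!is.na(i)]]
  }

  G <- prep$G
  # per-stratum log denominators; log-sum-exp stabilization only when the
  # linear predictor is large enough to threaten overflow
  parts <- function(beta) {
    eta <- drop(X %*% beta)
    if (max(abs(eta)) < 500) {
      ee <- exp(eta)
      denom <- drop(G %*% ee)
      list(eta = eta, ee = ee, denom = denom, logdenom = log(denom))
    } else {
      mx <- stratum_max(eta, sid, n_strata)
      ee <- exp(eta - mx[sid])
      denom <- drop(G %*% ee)
      list(eta = eta, ee = ee, denom = denom, logdenom = mx + log(denom))
    }
  }
  loglik_of <- function(pp) sum(w_row[y == 1] * pp$eta[y == 1]) -
    sum(sw * pp$logdenom)

  pp <- parts(beta)
  ll <- loglik_of(pp)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    pr <- pp$ee / pp$denom[sid]
    grad <- drop(crossprod(X, w_row * (y - pr)))
    M <- as.matrix(G %*% (pr * X))              # per-stratum mean covariates
    H <- crossprod(X, (w_row * pr) * X) - crossprod(M, sw * M)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) step <- solve(H + diag(1e-8, p), grad)
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * step
      pp_new <- parts(beta_new)
      ll_new <- loglik_of(pp_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { beta_new <- beta; pp_new <- pp; ll_new <- ll; break }
    }
    if (any(abs(beta_new) > beta_guard)) {
      worst <- covs[which.max(abs(beta_new))]
      abort(paste0("separation suspected: |coefficient| for `", worst,
                   "` exceeded ", beta_guard, " during fitting"))
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new; pp <- pp_new; ll <- ll_new
    if (max(abs(grad)) < 1e-6 && moved < tol) { converged <- TRUE; break }
  }

  pr <- pp$ee / pp$denom[sid]
  M <- as.matrix(G %*% (pr * X))
  H <- crossprod(X, (w_row * pr) * X) - crossprod(M, sw * M)
  Vc <- tryCatch(solve(H), error = function(e) NULL)
  se <- if (converged && !is.null(Vc)) sqrt(pmax(diag(Vc), 0)) else
    rep(NA_real_, p)

  structure(list(
    coefficients = setNames(beta, covs),
    se = setNames(se, covs),
    vcov = Vc,
    loglik = ll,
    null_loglik = -sum(sw * log(counts)),
    converged = converged,
    iterations = iter,
    n_strata = n_strata,
    dropped = dropped,
    terms = covs
  ), class = "bs_clogit")
}

# per-group max of a vector, groups 1..n_groups (slow path; only used
# when linear predictors are extreme)
stratum_max <- function(x, g, n_groups) {
  out <- rep(-Inf, n_groups)
  for (i in seq_along(x)) if (x[i] > out[g[i]]) out[g[i]] <- x[i]
  out
}

#' @export
print.bs_clogit <- function(x, ...) {
  cat("<bs_clogit> ", x$n_strata, " strata, logLik ", format(x$loglik),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bs_clogit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = x$terms,
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$coefficients / x$se),
    p.value = 2 * stats::pnorm(-abs(unname(x$coefficients / x$se)))
  )
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' @exportS3Method generics::glance
glance.bs_clogit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, null.logLik = x$null_loglik,
                 n.strata = x$n_strata, converged = x$converged,
                 iterations = x$iterations)
}

#' Stratum bootstrap for conditional logistic fits
#'
#' Resamples *strata* (not rows) with replacement `B` times, refits the
#' conditional logistic model on each replicate (as a weighted fit with
#' multinomial stratum counts, warm-started at the point estimate), and
#' summarizes the per-term bootstrap mean and standard deviation over
#' converged replicates. More than 20% non-converged replicates is treated
#' as an unstable fit and raised as an error — near-unidentifiable strata
#' sets produce exactly the huge-SD estimates this guard surfaces.
#'
#' @inheritParams fit_clogit
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param keep_draws Keep the B x p matrix of replicate estimates (needed
#'   for percentile intervals).
#' @return An object of class `bs_clogit_boot`: `summary` tibble (term,
#'   boot_mean, boot_sd), `draws` (optional matrix), `n_converged`, `B`,
#'   `point` (the [fit_clogit()] object).
#' @export
bootstrap_clogit <- function(data, case = "case", stratum = "stratum",
                             B = 1000, seed = NULL, keep_draws = TRUE,
                             beta_guard = 15) {
  prep <- clogit_prepare(data, case, stratum)
  n_strata <- prep$n_strata
  if (n_strata < 10) abort("bootstrap needs at least 10 strata")
  point <- clogit_fit_prepared(prep, beta_guard = beta_guard)
  p <- length(point$terms)
  draws <- matrix(NA_real_, B, p, dimnames = list(NULL, point$terms))
  n_fail <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      wts <- tabulate(sample.int(n_strata, n_strata, replace = TRUE),
                      nbins = n_strata)
      fit <- tryCatch(
        clogit_fit_prepared(prep, stratum_weights = wts,
                            init = point$coefficients,
                            beta_guard = beta_guard),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        n_fail <- n_fail + 1L
      } else {
        draws[b, fit$terms] <- fit$coefficients
      }
    }
  })
  if (n_fail > 0.2 * B) {
    abort(sprintf(
      "unstable fit: %d of %d bootstrap replicates failed to converge",
      n_fail, B))
  }
  ok <- stats::complete.cases(draws)
  summary <- tibble::tibble(
    term = point$terms,
    boot_mean = unname(colMeans(draws[ok, , drop = FALSE])),
    boot_sd = unname(apply(draws[ok, , drop = FALSE], 2, sd))
  )
  structure(list(summary = summary,
                 draws = if (keep_draws) draws[ok, , drop = FALSE],
                 n_converged = sum(ok), B = B, point = point),
            class = "bs_clogit_boot")
}

#' @exportS3Method generics::tidy
tidy.bs_clogit_boot <- function(x, ...) x$summary

#' @export
print.bs_clogit_boot <- function(x, ...) {
  cat("<bs_clogit_boot> ", x$n_converged, "/", x$B,
      " converged replicates\n", sep = "")
  print(x$summary)
  invisible(x)
}
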