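#' Logistic regression with a per-individual random intercept
#'
#' Fits `y ~ X + (1 | group)` for binary `y` by maximizing the Laplace
#' approximation to the marginal likelihood: for a candidate random-effect
#' variance, fixed effects and group modes are found jointly by penalized
#' Newton (IRLS with a ridge on the group intercepts), and the approximate
#' marginal log likelihood
#' `Q(beta, u) - 1/2 sum_i log(1 + sigma^2 sum_j w_ij)` is profiled over
#' `log(sigma)` by one-dimensional optimization. This is the
#' use-availability resource-selection model with individual as the random
#' intercept.
#'
#' @param data Data frame with the response, group and covariate columns.
#' @param response Name of the 0/1 (or logical) response column.
#' @param group Name of the grouping (individual id) column.
#' @param covariates Character vector of covariate column names; factors
#'   are expanded by reference-level dummy coding. Defaults to all columns
#'   other than `response` and `group`.
#' @param beta_guard Separation guard on `|beta|`.
#' @param sigma_fixed Optional fixed random-intercept SD; when given, the
#'   outer variance optimization is skipped.
#' @return An object of class `bs_relogit`: `coefficients` (fixed effects,
#'   incl. `(Intercept)`), `se` (conditional SEs from the penalized
#'   information), `sigma_re` (random-intercept SD), `u` (group modes),
#'   `loglik` (Laplace), `converged`, `n`, `groups`.
#' @export
fit_logistic_re <- function(data, response = "case", group = "tag_id",
                            covariates = NULL, beta_guard = 15,
                            sigma_fixed = NULL) {
  y <- data[[response]]
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("response must be binary 0/1")
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups for a random intercept")
  covariates <- covariates %||% setdiff(names(data), c(response, group))
  ff <- stats::reformulate(covariates)
  X <- stats::model.matrix(ff, data = data)
  # reject covariates constant after coding (other than the intercept)
  if (ncol(X) > 1) {
    const <- apply(X[, -1, drop = FALSE], 2, function(v) max(v) == min(v))
    if (any(const)) {
      abort(paste0("constant covariate column(s) after coding: ",
                   paste(colnames(X)[-1][const], collapse = ", ")))
    }
  }
  Z <- stats::model.matrix(~ g - 1)
  n_g <- nlevels(g)
  p <- ncol(X)

  # inner penalized Newton for (beta, u) at fixed sigma^2; returns the
  # Laplace objective
  inner <- function(log_sigma, theta0) {
    s2 <- exp(2 * log_sigma)
    theta <- theta0
    TT <- cbind(X, Z)
    pen <- c(rep(0, p), rep(1 / s2, n_g))
    ll_pen <- -Inf
    conv <- FALSE
    for (it in seq_len(100L)) {
      eta <- drop(TT %*% theta)
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      grad <- drop(crossprod(TT, y - mu)) - pen * theta
      H <- crossprod(TT, w * TT)
      diag(H) <- diag(H) + pen
      step <- solve(H, grad)
      alpha <- 1
      obj <- function(th) {
        e <- drop(TT %*% th)
        sum(y * e - log1p(exp(e))) - sum(pen * th^2) / 2
      }
      cur <- obj(theta)
      repeat {
        th_new <- theta + alpha * step
        if (obj(th_new) >= cur - 1e-12) break
        alpha <- alpha / 2
        if (alpha < 1e-8) { th_new <- theta; break }
      }
      moved <- max(abs(th_new - theta))
      theta <- th_new
      if (any(abs(theta[seq_len(p)]) > beta_guard)) {
        worst <- colnames(X)[which.max(abs(theta[seq_len(p)]))]
        abort(paste0("separation suspected: |coefficient| for `", worst,
                     "` exceeded ", beta_guard))
      }
      if (moved < 1e-10) { conv <- TRUE; break }
    }
    eta <- drop(TT %*% theta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    wg <- drop(crossprod(Z, w))     # sum of weights per group
    q <- sum(y * eta - log1p(exp(eta))) -
      sum(theta[p + seq_len(n_g)]^2) / (2 * s2)
    la <- q - 0.5 * sum(log1p(s2 * wg))
    list(objective = la, theta = theta, converged = conv, w = w)
  }

  theta0 <- rep(0, p + n_g)
  if (is.null(sigma_fixed)) {
    opt <- optimize(function(ls) inner(ls, theta0)$objective,
                    interval = c(-6, 3), maximum = TRUE, tol = 1e-6)
    log_sigma <- opt$maximum
  } else {
    if (sigma_fixed <= 0) abort("`sigma_fixed` must be positive")
    log_sigma <- log(sigma_fixed)
  }
  fit <- inner(log_sigma, theta0)
  sigma_re <- exp(log_sigma)
  theta <- fit$theta
  beta <- theta[seq_len(p)]
  u <- theta[p + seq_len(n_g)]

  TT <- cbind(X, Z)
  pen <- c(rep(0, p), rep(1 / sigma_re^2, n_g))
  H <- crossprod(TT, fit$w * TT)
  diag(H) <- diag(H) + pen
  V <- tryCatch(solve(H), error = function(e) NULL)
  se <- if (!is.null(V)) sqrt(pmax(diag(V)[seq_len(p)], 0)) else
    rep(NA_real_, p)

  structure(list(
    coefficients = setNames(beta, colnames(X)),
    se = setNames(se, colnames(X)),
    sigma_re = sigma_re,
    u = setNames(u, levels(g)),
    loglik = fit$objective,
    converged = fit$converged,
    n = length(y),
    groups = levels(g),
    terms = colnames(X)
  ), class = "bs_relogit")
}

#' @export
print.bs_relogit <- function(x, ...) {
  cat("<bs_relogit> ", x$n, " obs, ", length(x$groups),
      " groups, random-intercept SD ", format(x$sigma_re, digits = 4),
      "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bs_relogit <- function(x, ...) {
  tibble::tibble(
    term = x$terms,
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$coefficients / x$se),
    p.value = 2 * stats::pnorm(-abs(unname(x$coefficients / x$se)))
  )
}

#' @exportS3Method generics::glance
glance.bs_relogit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, sigma.re = x$sigma_re, nobs = x$n,
                 n.groups = length(x$groups), converged = x$converged)
}
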