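#' Movement-kernel maximum likelihood: gamma step lengths
#'
#' Fits the gamma distribution by maximum likelihood via Newton iteration on
#' the profile score for the shape, `log(k) - digamma(k) = log(mean x) -
#' mean(log x)`; the scale then follows as `mean(x) / k`. This is the
#' step-length component of the selection-free movement kernel.
#'
#' @param x Positive step lengths (n >= 10).
#' @return An object of class `bs_gamma`: list with `shape`, `scale`,
#'   `loglik`, `n`, `iterations`, `converged`.
#' @export
fit_gamma <- function(x) {
  if (length(x) < 10) abort("fit_gamma needs at least 10 values")
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("fit_gamma requires strictly positive finite values")
  }
  s <- log(mean(x)) - mean(log(x))
  fit <- fit_gamma_suff(s)
  shape <- fit$shape
  scale <- mean(x) / shape
  ll <- sum(stats::dgamma(x, shape = shape, scale = scale, log = TRUE))
  structure(list(shape = shape, scale = scale, loglik = ll, n = length(x),
                 iterations = fit$iterations, converged = fit$converged),
            class = "bs_gamma")
}

#' @rdname fit_gamma
#' @param s The gamma sufficient-statistic gap `log(mean x) - mean(log x)`
#'   (> 0 unless all values are equal). Exposed so the estimator can be
#'   verified directly against analytic sufficient statistics.
#' @export
fit_gamma_suff <- function(s) {
  if (!is.finite(s) || s <= 0) {
    abort("degenerate sample: zero variance (gamma shape unbounded)")
  }
  # Minka-style initialisation, then Newton on log(k) - digamma(k) - s = 0
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    g <- log(k) - digamma(k) - s
    h <- 1 / k - trigamma(k)
    step <- g / h
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    k <- k_new
    if (abs(log(k) - digamma(k) - s) < 1e-10) { converged <- TRUE; break }
  }
  list(shape = k, iterations = iter, converged = converged)
}

#' Movement-kernel maximum likelihood: von Mises turning angles
#'
#' Fits the concentration `kappa` of a von Mises distribution with mean
#' fixed at zero (turning angles are modelled as symmetric about straight
#' ahead). The MLE solves `A(kappa) = I1(kappa)/I0(kappa) = mean(cos
#' angle)`, inverted numerically. A negative mean cosine gives `kappa = 0`
#' (no concentration toward zero); near-degenerate samples are capped at
#' `kappa_max`.
#'
#' @param theta Angles in radians (n >= 10).
#' @param kappa_max Documented cap for degenerate all-equal-angle samples.
#' @return An object of class `bs_vonmises`: list with `mu` (0), `kappa`,
#'   `rbar`, `loglik`, `n`.
#' @export
fit_vonmises <- function(theta, kappa_max = 500) {
  if (length(theta) < 10) abort("fit_vonmises needs at least 10 angles")
  if (any(!is.finite(theta))) abort("angles must be finite")
  rbar <- mean(cos(theta))
  kappa <- fit_vonmises_suff(rbar, kappa_max)
  ll <- sum(dvonmises(theta, kappa, log = TRUE))
  structure(list(mu = 0, kappa = kappa, rbar = rbar, loglik = ll,
                 n = length(theta)),
            class = "bs_vonmises")
}

#' @rdname fit_vonmises
#' @param rbar The sufficient statistic `mean(cos theta)`.
#' @export
fit_vonmises_suff <- function(rbar, kappa_max = 500) {
  if (rbar <= 0) return(0)
  if (rbar >= vonmises_A(kappa_max)) return(kappa_max)
  uniroot(function(k) vonmises_A(k) - rbar, c(1e-12, kappa_max),
          tol = 1e-12)$root
}

# A(kappa) = I1/I0, computed with scaled Bessel functions for stability
vonmises_A <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' von Mises density, distribution and random generation (mean 0)
#'
#' @param theta,q Angles in radians.
#' @param kappa Concentration (>= 0).
#' @param log Return log density?
#' @param n Number of draws.
#' @return Density values, CDF values on `(-pi, pi]`, or draws in
#'   `(-pi, pi]`.
#' @export
dvonmises <- function(theta, kappa, log = FALSE) {
  ld <- kappa * (cos(theta) - 1) - log(2 * pi) -
    log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' @rdname dvonmises
#' @export
pvonmises <- function(q, kappa) {
  vapply(q, function(b) {
    if (b <= -pi) return(0)
    if (b >= pi) return(1)
    stats::integrate(dvonmises, -pi, b, kappa = kappa,
                     rel.tol = 1e-10)$value
  }, numeric(1))
}

#' @rdname dvonmises
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 1e-10) return(runif(n, -pi, pi))
  # Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[got + seq_len(k)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + k
    }
  }
  out
}

#' @exportS3Method generics::tidy
tidy.bs_gamma <- function(x, ...) {
  tibble::tibble(term = c("shape", "scale"),
                 estimate = c(x$shape, x$scale))
}

#' @exportS3Method generics::tidy
tidy.bs_vonmises <- function(x, ...) {
  tibble::tibble(term = c("mu", "kappa"), estimate = c(x$mu, x$kappa))
}

#' @exportS3Method generics::glance
glance.bs_gamma <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, converged = x$converged)
}

#' @exportS3Method generics::glance
glance.bs_vonmises <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, rbar = x$rbar)
}
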