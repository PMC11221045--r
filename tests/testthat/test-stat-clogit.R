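test_that("the two-strata worked example has the closed-form solution", {
  # stratum 1: case has x = 1, controls x = 0, 0
  # stratum 2: case has x = 0, controls x = 1, 0
  d <- tibble::tibble(
    stratum = c(1, 1, 1, 2, 2, 2),
    case = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    x = c(1, 0, 0, 0, 1, 0)
  )
  fit <- fit_clogit(d)
  expect_lt(abs(unname(fit$coefficients) - log(2)), 1e-6)
})

test_that("the Newton fit agrees with a grid-search likelihood oracle", {
  set.seed(41)
  for (i in 1:10) {
    d <- random_strata_1d(n_strata = sample(8:20, 1),
                          n_controls = sample(2:5, 1),
                          beta = runif(1, -1.5, 1.5))
    oracle <- clogit_grid_oracle(d)
    fit <- fit_clogit(d)
    expect_lt(abs(unname(fit$coefficients) - oracle$beta), 2e-3)
    # oracle dominance: the MLE's likelihood beats every grid point
    expect_gte(fit$loglik + 1e-10, oracle$loglik)
  }
})

test_that("stratum-constant covariates are dropped and shifts are inert", {
  set.seed(42)
  d <- random_strata_1d(15, beta = 0.6)
  d$const <- as.numeric(factor(d$stratum)) * 2   # constant within stratum
  fit <- fit_clogit(d)
  expect_equal(fit$dropped, "const")
  expect_false("const" %in% fit$terms)
  # adding a stratum-constant offset to x leaves the estimate unchanged
  d2 <- d
  d2$x <- d2$x + 10 * as.numeric(factor(d2$stratum))
  fit2 <- fit_clogit(d2)
  expect_equal(unname(fit$coefficients["x"]),
               unname(fit2$coefficients["x"]), tolerance = 1e-10)
  expect_error(fit_clogit(d[, c("stratum", "case", "const")]),
               "no covariate varies")
})

test_that("within-stratum choice probabilities sum to one at the MLE", {
  set.seed(43)
  d <- random_strata_1d(12, beta = 0.5)
  fit <- fit_clogit(d)
  eta <- unname(fit$coefficients["x"]) * d$x
  psums <- vapply(split(seq_len(nrow(d)), d$stratum), function(i)
    sum(exp(eta[i]) / sum(exp(eta[i]))), numeric(1))
  expect_equal(unname(psums), rep(1, 12), tolerance = 1e-12)
})

test_that("separation is surfaced as an error naming the term", {
  d <- purrr::map_dfr(1:12, function(s) {
    tibble::tibble(stratum = s, case = c(TRUE, FALSE, FALSE),
                   x = c(1, 0, 0))   # case always maximal
  })
  expect_error(fit_clogit(d), "separation.*`x`")
})

test_that("the stratum bootstrap is seeded, consistent and degenerate-exact", {
  set.seed(44)
  d <- random_strata_1d(40, n_controls = 4, beta = 0.8)
  b1 <- bootstrap_clogit(d, B = 120, seed = 5)
  b2 <- bootstrap_clogit(d, B = 120, seed = 5)
  expect_identical(b1$summary, b2$summary)
  # bootstrap mean close to the point estimate
  expect_lt(abs(b1$summary$boot_mean - unname(b1$point$coefficients)),
            2 * b1$summary$boot_sd / sqrt(120) * 10)
  # identical strata: zero spread
  one <- tibble::tibble(stratum = 1, case = c(TRUE, FALSE, FALSE),
                        x = c(0.5, 0, 1))
  same <- purrr::map_dfr(1:15, function(s) { o <- one; o$stratum <- s; o })
  bs <- bootstrap_clogit(same, B = 40, seed = 6)
  expect_equal(bs$summary$boot_sd, 0, tolerance = 1e-10)
  expect_error(bootstrap_clogit(d[d$stratum <= 5, ], B = 10),
               "at least 10 strata")
})

test_that("weighted refits equal refits on duplicated strata", {
  set.seed(45)
  d <- random_strata_1d(20, beta = 0.7)
  wts <- c(rep(2, 5), rep(0, 5), rep(1, 10))
  fw <- fit_clogit(d, stratum_weights = wts)
  dd <- purrr::map_dfr(which(wts > 0), function(s) {
    purrr::map_dfr(seq_len(wts[s]), function(k) {
      o <- d[d$stratum == s, ]
      o$stratum <- paste0(s, "_", k)
      o
    })
  })
  fd <- fit_clogit(dd)
  expect_equal(unname(fw$coefficients), unname(fd$coefficients),
               tolerance = 1e-8)
  expect_equal(fw$loglik, fd$loglik, tolerance = 1e-8)
})

test_that("clogit matches the survival package on a shared design", {
  skip_if_not_installed("survival")
  set.seed(46)
  d <- purrr::map_dfr(1:40, function(s) {
    x <- rnorm(5); z <- rnorm(5)
    pick <- sample(5, 1, prob = exp(0.8 * x - 0.5 * z))
    tibble::tibble(stratum = s, case = seq_len(5) == pick, x = x, z = z)
  })
  mine <- fit_clogit(d)
  # one case per stratum: the Cox partial likelihood with stratification
  # is exactly the conditional logistic likelihood
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(d)), case) ~ x + z +
      survival::strata(stratum),
    data = d, ties = "breslow")
  expect_equal(unname(mine$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
})
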