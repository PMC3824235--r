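## small data builder: record generated directly from known covariate effects
gamma_fixture <- function(n = 4000, gamma_T = 3, beta_R = 0.75, noise = 0,
                          t_noise = 0.4, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  T_i <- t_noise * rnorm(n) + gamma_T * z
  mk <- function(sd_extra) {
    cbind(T_i + rnorm(n, 0, 0.3 + sd_extra), T_i + rnorm(n, 0, 0.3 + sd_extra))
  }
  R <- beta_R * cbind(T_i, T_i) + matrix(rnorm(2 * n, 0, noise), n, 2)
  me_data(Q = mk(0.1), R = R, M = mk(0.2) * 10,
          Z_T = matrix(z, ncol = 1, dimnames = list(NULL, "z")))
}

test_that("gamma_T is the mixed-model slope divided by beta_R", {
  ## noiseless record (R = 0.75 * 3 z exactly): the slope is beta_R * gamma_T
  d <- gamma_fixture(n = 800, gamma_T = 3, beta_R = 0.75, noise = 0,
                     t_noise = 0)
  g <- suppressWarnings(estimate_gamma_T(d, sensitivity_setting(beta_R = 0.75)))
  expect_equal(g$estimate, 3, tolerance = 1e-6)

  ## halving beta_R doubles the returned coefficient exactly on fixed data
  d2 <- gamma_fixture(n = 800, gamma_T = 3, beta_R = 0.75, noise = 0.3)
  ga <- estimate_gamma_T(d2, sensitivity_setting(beta_R = 0.75))
  gb <- estimate_gamma_T(d2, sensitivity_setting(beta_R = 0.375))
  expect_equal(gb$estimate, 2 * ga$estimate, tolerance = 1e-10)
  expect_equal(gb$se, 2 * ga$se, tolerance = 1e-10)
})

test_that("a null covariate effect is estimated near zero with honest SEs", {
  ## z-scores over several independent replicates: calibrated near N(0, 1)
  zs <- vapply(1:5, function(s) {
    d <- gamma_fixture(n = 4000, gamma_T = 0, beta_R = 1, noise = 0.4,
                       seed = s)
    g <- estimate_gamma_T(d, sensitivity_setting())
    g$estimate / g$se
  }, numeric(1))
  expect_lt(max(abs(zs)), 4)
  expect_lt(mean(abs(zs)), 2)
})

test_that("secondary covariate effects are recovered from the constructed response", {
  s <- sensitivity_setting()
  p <- fv_example_params(s)
  p$gamma_Q <- c(0.1, -0.2)
  cov_spec <- list(Z_Q = list(list(type = "continuous"),
                              list(type = "continuous")))
  d <- gen_dataset(simulation_spec(n = 10000, params = p, sens = s,
                                   covariates = cov_spec, seed = 15))
  fit <- fit_ml(residualize(d), s)
  g <- estimate_gamma_secondary(d, fit, "Q")
  for (k in 1:2)
    expect_lt(abs(g$estimate[k] - p$gamma_Q[k]), 3 * g$se[k])

  ## permuting the covariate rows destroys the association
  d_perm <- d
  set.seed(16)
  perm <- sample(d$n)
  d_perm$Z_Q <- lapply(d$Z_Q, function(m) m[perm, , drop = FALSE])
  g0 <- estimate_gamma_secondary(d_perm, fit, "Q")
  for (k in 1:2)
    expect_lt(abs(g0$estimate[k]), 3 * g0$se[k])
})

test_that("a response built to be identically zero gives zero coefficients", {
  ## Q constructed as exactly (beta_Q / beta_R) * R
  n <- 300
  set.seed(21)
  T_i <- rnorm(n)
  R <- cbind(T_i, T_i) + matrix(rnorm(2 * n, 0, 0.2), n, 2)
  Q <- 0.66 * R
  d <- me_data(Q = Q, R = R, M = 10 * R + matrix(rnorm(2 * n), n, 2),
               Z_Q = matrix(rnorm(n), ncol = 1))
  fit <- structure(list(params = me_params(J = 2, beta_Q = 0.66),
                        sens = sensitivity_setting(), converged = TRUE,
                        map = NULL), class = "me_fit")
  g <- suppressWarnings(suppressMessages(estimate_gamma_secondary(d, fit, "Q")))
  expect_equal(g$estimate, 0, tolerance = 1e-8)
})

test_that("missing inputs are refused cleanly", {
  d <- gamma_fixture(n = 100)
  expect_error(estimate_gamma_T(residualize(d), sensitivity_setting()),
               "residualized")
  d2 <- d; d2$Z_T <- lapply(d2$Z_T, function(m) m[, 0, drop = FALSE])
  expect_error(estimate_gamma_T(d2, sensitivity_setting()), "Z_T")
})
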