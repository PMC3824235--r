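test_that("residualization centers, decorrelates, and flags rank deficiency", {
  p <- fv_example_params()
  ## no covariates: residualize just removes per-column means
  d <- gen_dataset(simulation_spec(n = 500, params = p, seed = 41))
  dr <- residualize(d)
  expect_equal(max(abs(colMeans(obs_matrix(dr)))), 0, tolerance = 1e-10)
  expect_equal(cov(obs_matrix(dr)), cov(obs_matrix(d)), tolerance = 1e-10)

  ## X = 2 + 3 z + noise: residuals uncorrelated with z
  set.seed(42)
  n <- 5000
  z <- rnorm(n)
  p2 <- fv_example_params(); p2$gamma_T <- 3
  d2 <- gen_dataset(simulation_spec(n = n, params = p2, seed = 43,
                                    covariates = list(Z_T = list(
                                      list(type = "continuous")))))
  z <- d2$Z_T[[1]][, 1]
  dr2 <- residualize(d2)
  for (j in 1:2)
    expect_lt(abs(cor(dr2$R[, j], z)), 3 / sqrt(n))

  ## duplicated covariate column: rank deficiency is named
  d3 <- d2
  d3$Z_T <- lapply(d3$Z_T, function(m) cbind(m, dup = m[, 1]))
  expect_error(residualize(d3), "collinear")
})

test_that("log-likelihood matches analytic values and is additive", {
  ## 6 observed zeros, zero mean, identity covariance: -3 log(2 pi)
  p <- me_params(J = 2, beta_Q = 0, beta_M = 0, sigma2_T = 1e-18,
                 sigma2_h = 0, sigma2_Q = 1, sigma2_R = 1, sigma2_M = 1)
  d1 <- me_data(Q = matrix(0, 1, 2), R = matrix(0, 1, 2), M = matrix(0, 1, 2))
  expect_equal(loglik(p, sensitivity_setting(), d1), -3 * log(2 * pi),
               tolerance = 1e-8)

  ## additivity over a split, and invariance to row order
  s <- sensitivity_setting(0.75, 0.2)
  pp <- rand_valid_params(61, sens = s)
  d <- gen_dataset(simulation_spec(n = 400, params = pp, sens = s, seed = 62,
                                   missingness = list(mechanism = "mcar",
                                                      rates = 0.2)))
  ll_all <- loglik(pp, s, d)
  ll_a <- loglik(pp, s, subset_me_data(d, 1:150))
  ll_b <- loglik(pp, s, subset_me_data(d, 151:d$n))
  expect_equal(ll_all, ll_a + ll_b, tolerance = 1e-8)
  perm <- sample(d$n)
  expect_equal(loglik(pp, s, subset_me_data(d, perm)), ll_all,
               tolerance = 1e-8)
})

test_that("pattern-grouped likelihood equals the individual-level density sum", {
  s <- sensitivity_setting(1, 0.2)
  p <- rand_valid_params(63, sens = s)
  d <- gen_dataset(simulation_spec(n = 120, params = p, sens = s, seed = 64,
                                   missingness = list(mechanism = "mcar",
                                                      rates = 0.3)))
  m <- build_implied_moments(p, s)
  obs <- obs_matrix(d)
  ll_oracle <- 0
  for (i in seq_len(d$n)) {
    ok <- !is.na(obs[i, ])
    ll_oracle <- ll_oracle + oracle_mvn_loglik(obs[i, ok, drop = FALSE],
                                               m$mean[ok],
                                               m$cov[ok, ok, drop = FALSE])
  }
  expect_equal(loglik(p, s, d), ll_oracle, tolerance = 1e-8)
})

test_that("non-PD parameters give the -Inf sentinel, not an error", {
  p <- me_params(J = 2, rho_QQ = 0.9, rho_RR = 0.9,
                 rho_QR_same = c(-0.9, -0.9), rho_QR_diff = 0.85)
  d <- gen_dataset(simulation_spec(n = 50, params = fv_example_params(),
                                   seed = 3))
  expect_identical(loglik(p, sensitivity_setting(), d), -Inf)
})

test_that("the ML fit recovers generating parameters and is a local optimum", {
  s <- sensitivity_setting()
  p <- fv_example_params(s)
  d <- residualize(gen_dataset(simulation_spec(n = 8000, params = p, sens = s,
                                               seed = 71)))
  fit <- fit_ml(d, s)
  expect_true(fit$converged)
  tab <- natural_se(fit)
  truth <- c(beta_Q = p$beta_Q, beta_M = p$beta_M, sigma2_T = p$sigma2_T,
             sigma2_h1 = p$sigma2_h[1], sigma2_h2 = p$sigma2_h[2],
             sigma2_Q1 = p$sigma2_Q[1], sigma2_M2 = p$sigma2_M[2],
             rho_QQ_12 = 0.65, rho_QR_same1 = 0.45)
  for (nm in names(truth)) {
    row <- tab[tab$parameter == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]) / row$se, 3.5, label = nm)
  }
  ## local optimality: random perturbations of theta do not improve loglik
  pstats_ll <- function(theta) {
    prm <- dietme:::unpack_theta(theta, fit$map, fit$template)
    loglik(prm, s, d)
  }
  set.seed(72)
  for (k in 1:20) {
    th <- fit$theta + rnorm(length(fit$theta), 0, 0.05)
    expect_lt(pstats_ll(th), fit$loglik + 1e-6)
  }
})

test_that("near-noiseless data recover the scaling ratio in a degenerate limit", {
  s <- sensitivity_setting(0.8, 0)
  p <- me_params(J = 2, beta_Q = 0.6, beta_M = 2, sigma2_T = 0.5,
                 sigma2_h = c(0.01, 0.01), sigma2_Q = 1e-4, sigma2_R = 1e-4,
                 sigma2_M = 1e-4)
  d <- residualize(gen_dataset(simulation_spec(n = 4000, params = p, sens = s,
                                               seed = 81)))
  fit <- fit_ml(d, s)
  expect_equal(fit$params$beta_Q / s$beta_R, 0.75, tolerance = 0.005)
})

test_that("unidentified designs are refused with the counting report", {
  p1 <- me_params(J = 1, sigma2_T = 0.5)
  d1 <- gen_dataset(simulation_spec(n = 300, params = p1, seed = 91))
  expect_error(fit_ml(d1, sensitivity_setting()), "not identified")
  ## fixing the same-time correlation makes the fit possible
  fit <- fit_ml(d1, sensitivity_setting(),
                constraints = list(rho_QR_same = 0))
  expect_true(fit$converged)
})

test_that("refitting residualized data with free intercepts estimates them near zero", {
  s <- sensitivity_setting()
  d <- residualize(gen_dataset(simulation_spec(n = 4000,
                                               params = fv_example_params(),
                                               seed = 95)))
  fit <- fit_ml(d, s, intercepts = "free")
  ## the MVN mean MLE is the sample mean, which residualization sets to 0,
  ## so the free intercepts must vanish up to optimizer tolerance
  a <- c(fit$params$alpha_Q, fit$params$alpha_R, fit$params$alpha_M)
  expect_lt(max(abs(a)), 0.05)
})
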