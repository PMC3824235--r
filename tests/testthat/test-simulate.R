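test_that("covariate generation is reproducible and respects its spec", {
  cov_spec <- list(Z_T = list(list(type = "binary", p = 0.5),
                              list(type = "continuous", mean = 58, sd = 9)),
                   Z_Q = NULL,
                   Z_M = list(list(type = "categorical", probs = c(0.5, 0.3, 0.2))))
  p <- fv_example_params()
  p$gamma_T <- c(0.1, 0.01); p$gamma_M <- c(1, -1)
  spec <- simulation_spec(n = 100000, params = p, covariates = cov_spec,
                          seed = 31)
  b1 <- gen_covariates(spec)
  b2 <- gen_covariates(spec)
  expect_identical(b1, b2)
  expect_equal(ncol(b1$Z_T[[1]]), 2L)
  expect_equal(ncol(b1$Z_Q[[1]]), 0L)
  expect_equal(ncol(b1$Z_M[[1]]), 2L)  # 3 levels -> 2 dummies
  ## binomial check on the binary column
  expect_lt(abs(mean(b1$Z_T[[1]][, 1]) - 0.5), 3 * sqrt(0.25 / spec$n))
  ## time-constant columns repeat across time points
  expect_identical(b1$Z_T[[1]], b1$Z_T[[2]])
})

test_that("generated data reproduce the implied moments (moment oracle)", {
  s <- sensitivity_setting(0.75, 0.4)
  p <- rand_valid_params(202, sens = s)
  spec <- simulation_spec(n = 200000, params = p, sens = s, seed = 77)
  d <- gen_dataset(spec)
  m <- build_implied_moments(p, s)
  S <- cov(obs_matrix(d))
  se <- mc_cov_se(m$cov, spec$n)
  expect_lt(max(abs(S - m$cov) / se), 4)
  expect_lt(max(abs(colMeans(obs_matrix(d)) - m$mean) /
                  sqrt(diag(m$cov) / spec$n)), 4)
})

test_that("latent truth behaves as specified and does not leak", {
  s <- sensitivity_setting(1, 0.4)
  p <- fv_example_params(s)
  spec <- simulation_spec(n = 150000, params = p, sens = s, seed = 13)
  d <- gen_dataset(spec)
  tr <- attr(d, "truth")
  expect_equal(var(tr$T), p$sigma2_T, tolerance = 0.03)
  ## biomarker error correlation: residuals of M on T_time recover rho_MM
  e1 <- d$M[, 1] - p$beta_M * tr$T_time[, 1]
  e2 <- d$M[, 2] - p$beta_M * tr$T_time[, 2]
  r <- cor(e1, e2)
  expect_lt(abs(r - 0.4), 3.5 * (1 - r^2) / sqrt(spec$n))
  ## self-report and biomarker errors are uncorrelated
  eq <- d$Q[, 1] - p$alpha_Q[1] - p$beta_Q * tr$T_time[, 1]
  expect_lt(abs(cor(eq, e1 - mean(e1))), 3.5 / sqrt(spec$n))

  ## truth is identical when only the missingness seed changes
  spec_m <- simulation_spec(n = 150000, params = p, sens = s, seed = 13,
                            missingness = list(mechanism = "mcar",
                                               rates = c(M2 = 0.3)))
  d2 <- gen_dataset(spec_m)
  expect_identical(attr(d2, "truth")$T, tr$T)
})

test_that("degenerate no-error generation gives perfectly correlated slots", {
  p <- me_params(J = 2, beta_Q = 1, beta_M = 1, sigma2_T = 1, sigma2_h = 0,
                 sigma2_Q = 1e-12, sigma2_R = 1e-12, sigma2_M = 1e-12)
  d <- gen_dataset(simulation_spec(n = 2000, params = p, seed = 5))
  expect_equal(cor(d$Q[, 1], d$M[, 1]), 1, tolerance = 1e-6)
})

test_that("missingness mechanisms do what they claim", {
  p <- fv_example_params()
  spec0 <- simulation_spec(n = 100000, params = p, seed = 21)
  d0 <- gen_dataset(spec0)

  ## rate 0 is the identity
  d_same <- apply_missingness(d0, list(mechanism = "mcar", rates = c(M2 = 0)),
                              seed = 1)
  expect_identical(obs_matrix(d_same), obs_matrix(d0))

  ## MCAR: observed fraction binomial around 1 - rate
  d_m <- apply_missingness(d0, list(mechanism = "mcar", rates = c(M2 = 0.3)),
                           seed = 2)
  frac <- mean(!is.na(d_m$M[, 2]))
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.21 / d0$n))

  ## MAR driven by Q1: deletion indicator correlates with the driver,
  ## and the driver stays observed
  d_mar <- apply_missingness(d0, list(mechanism = "mar", slots = c("R2", "M2"),
                                      driver = "Q1", intercept = -0.6,
                                      slope = 2), seed = 3)
  del <- is.na(d_mar$R[, 2])
  r <- cor(del, d_mar$Q[, 1])
  expect_gt(abs(r), 3 / sqrt(d0$n))
  expect_false(anyNA(d_mar$Q[, 1]))

  ## the driver must remain observed by construction
  expect_error(simulation_spec(n = 10, params = p,
                               missingness = list(mechanism = "mar",
                                                  slots = "Q1", driver = "Q1",
                                                  intercept = 0, slope = 1)),
               "driver")
})

test_that("artifact injection hits the expected number of cells", {
  p <- fv_example_params()
  spec <- simulation_spec(n = 50000, params = p, raw = TRUE, seed = 9)
  d <- gen_dataset(spec)
  d2 <- inject_artifacts(d, list(zero_rate = 0.01, outlier_rate = 0.02,
                                 outlier_factor = 10), seed = 4)
  nz <- sum(d2$Q == 0) + sum(d2$R == 0)
  n_cells <- 2 * length(d$Q)
  expect_lt(abs(nz - 0.01 * n_cells), 3 * sqrt(0.0099 * n_cells))
  ## identity at zero rates
  d3 <- inject_artifacts(d, list(zero_rate = 0, outlier_rate = 0), seed = 4)
  expect_identical(obs_matrix(d3), obs_matrix(d))
  ## refuses analysis-scale input
  expect_error(inject_artifacts(gen_dataset(simulation_spec(100, p, seed = 2)),
                                list(zero_rate = 0.1)), "raw")
})

test_that("pattern grouping partitions the cohort", {
  p <- fv_example_params()
  d <- gen_dataset(simulation_spec(n = 1000, params = p, seed = 8))
  pats <- group_patterns(d)
  expect_length(pats, 1L)
  expect_equal(pats[[1]]$n, 1000L)

  d$M[1, 2] <- NA
  pats2 <- group_patterns(d)
  expect_length(pats2, 2L)
  expect_equal(sum(vapply(pats2, `[[`, numeric(1), "n")), 1000)

  ## heavy elementwise missingness still partitions exactly
  dm <- apply_missingness(d, list(mechanism = "mcar", rates = 0.5), seed = 6)
  pats3 <- group_patterns(dm)
  expect_equal(sum(vapply(pats3, `[[`, numeric(1), "n")), dm$n)
})
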