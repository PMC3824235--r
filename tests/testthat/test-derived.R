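test_that("classical-error limit gives the textbook attenuation factor", {
  p <- me_params(J = 1, beta_Q = 1, sigma2_T = 1, sigma2_Q = 1)
  expect_equal(rdr(p, sensitivity_setting(), "Q", 1), 0.5)
  ## correlation in the same limit: 1 / sqrt(2)
  expect_equal(corr_with_true(p, sensitivity_setting(), "Q", 1), 1 / sqrt(2))
})

test_that("perfect measurement gives correlation 1 and RDR 1", {
  p <- me_params(J = 2, beta_Q = 1, beta_M = 1, sigma2_T = 1, sigma2_h = 0,
                 sigma2_Q = 1e-12, sigma2_R = 1e-12, sigma2_M = 1e-12)
  s <- sensitivity_setting()
  for (X in c("Q", "R", "M"))
    expect_equal(corr_with_true(p, s, X, 1), 1, tolerance = 1e-9)
  expect_equal(rdr(p, s, "Q", 2), 1, tolerance = 1e-9)
})

test_that("rescaling beta_R divides the record RDR and leaves correlations unchanged", {
  ## the compensating reparameterization that refitting produces:
  ## beta_Q, beta_M scaled by c, intake variances by 1/c^2
  base <- fv_example_params(sensitivity_setting(1, 0))
  for (c_ in c(0.75, 0.5)) {
    sc <- sensitivity_setting(c_, 0)
    p <- fv_example_params(sc)
    for (j in 1:2) for (X in c("Q", "R")) for (e in c("longterm", "timespecific")) {
      expect_equal(rdr(p, sc, X, j, e),
                   rdr(base, sensitivity_setting(1, 0), X, j, e) / c_,
                   tolerance = 1e-10)
    }
    for (j in 1:2) for (X in c("Q", "R", "M"))
      expect_equal(corr_with_true(p, sc, X, j),
                   corr_with_true(base, sensitivity_setting(1, 0), X, j),
                   tolerance = 1e-10)
  }
})

test_that("time-specific RDR dominates the long-term RDR when sigma2_h > 0", {
  for (seed in 1:8) {
    p <- rand_valid_params(seed)
    s <- sensitivity_setting()
    for (X in c("Q", "R")) for (j in 1:2) {
      expect_gt(rdr(p, s, X, j, "timespecific"), rdr(p, s, X, j, "longterm"))
    }
  }
})

test_that("closed-form RDR and correlation match the brute-force simulation oracle", {
  s <- sensitivity_setting(0.75, 0.2)
  p <- rand_valid_params(101, sens = s)
  spec <- simulation_spec(n = 300000, params = p, sens = s, seed = 55)
  d <- gen_dataset(spec)
  tr <- attr(d, "truth")
  for (X in c("Q", "R")) for (j in 1:2) {
    x <- d[[X]][, j]
    ## long-term: slope of T_i on X_ij
    o <- slope_with_se(tr$T, x)
    expect_lt(abs(rdr(p, s, X, j, "longterm") - o["slope"]), 3.5 * o["se"])
    ## time-specific: slope of T_ij on X_ij
    o2 <- slope_with_se(tr$T_time[, j], x)
    expect_lt(abs(rdr(p, s, X, j, "timespecific") - o2["slope"]), 3.5 * o2["se"])
  }
  n <- length(tr$T)
  for (X in c("Q", "R", "M")) for (j in 1:2) {
    r_hat <- cor(d[[X]][, j], tr$T)
    se_r <- (1 - r_hat^2) / sqrt(n)
    expect_lt(abs(corr_with_true(p, s, X, j, "longterm") - r_hat), 3.5 * se_r)
  }
})

test_that("degenerate instruments are rejected", {
  p <- me_params(J = 1, beta_Q = 0, sigma2_T = 1)
  expect_error(rdr(p, sensitivity_setting(), "Q", 1), "degenerate")
})

test_that("back-transformed RDR is 1 for exact measurement and matches the lognormal closed form", {
  s <- sensitivity_setting()
  p0 <- me_params(J = 1, beta_Q = 1, sigma2_T = 1, sigma2_Q = 1e-10,
                  sigma2_R = 1, sigma2_M = 1)
  bt0 <- backtransform_rdr(p0, s, "Q", 1, n_mc = 5e4, seed = 2)
  expect_equal(as.numeric(bt0), 1, tolerance = 1e-4)

  ## classical error on the log scale: closed-form slope from the
  ## moment-generating function of the bivariate normal
  p1 <- me_params(J = 1, beta_Q = 1, sigma2_T = 1, sigma2_Q = 1,
                  sigma2_R = 1, sigma2_M = 1)
  vT <- 1; vX <- 2; cv <- 1
  closed <- (exp(cv) - 1) * exp((vT + vX) / 2) / ((exp(vX) - 1) * exp(vX))
  bt1 <- backtransform_rdr(p1, s, "Q", 1, n_mc = 2e5, seed = 9)
  expect_lt(abs(as.numeric(bt1) - closed), 3 * attr(bt1, "mc_se"))

  ## doubling n_mc moves the estimate by less than 3 MC SEs
  bt2 <- backtransform_rdr(p1, s, "Q", 1, n_mc = 4e5, seed = 9)
  expect_lt(abs(as.numeric(bt2) - as.numeric(bt1)), 3 * attr(bt1, "mc_se"))
  expect_error(backtransform_rdr(p1, s, "Q", 1, n_mc = 100), "1e4")
})

test_that("derived_quantities tabulates every instrument, time and exposure", {
  p <- rand_valid_params(7)
  tab <- derived_quantities(p, sensitivity_setting())
  expect_equal(sum(tab$quantity == "rdr"), 2 * 2 * 2)
  expect_equal(sum(tab$quantity == "corr"), 3 * 2 * 2)
  expect_true(all(abs(tab$estimate[tab$quantity == "corr"]) <= 1))
  expect_true(all(is.finite(tab$estimate)))
})
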