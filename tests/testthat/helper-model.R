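## shared fixtures: all test data are generated in code

## a random valid parameter draw (J = 2): variances on realistic scales,
## correlations modest enough that the error-correlation matrix is PD
rand_valid_params <- function(seed, J = 2L, sens = sensitivity_setting()) {
  set.seed(seed)
  repeat {
    p <- me_params(
      J = J,
      beta_Q = runif(1, 0.3, 1.5), beta_M = runif(1, 5, 60),
      sigma2_T = runif(1, 0.05, 0.5),
      sigma2_h = runif(J, 0.005, 0.1),
      sigma2_Q = runif(J, 0.1, 0.5), sigma2_R = runif(J, 0.1, 0.5),
      sigma2_M = runif(J, 50, 300),
      rho_QQ = runif(1, 0, 0.6), rho_RR = runif(1, 0, 0.6),
      rho_QR_same = runif(J, 0, 0.5),
      rho_QR_diff = runif(J * (J - 1L), 0, 0.4),
      alpha_Q = runif(J, 4, 7), alpha_R = runif(J, 4, 7),
      alpha_M = runif(J, 40, 70))
    ok <- tryCatch({ validate_me_params(p, sens); TRUE },
                   error = function(e) FALSE)
    if (ok) return(p)
  }
}

## Monte-Carlo standard errors of sample covariance entries under
## normality: se(S_jk) = sqrt((Sigma_jj Sigma_kk + Sigma_jk^2) / n)
mc_cov_se <- function(Sigma, n) {
  sqrt((tcrossprod(diag(Sigma)) + Sigma^2) / n)
}

## independent multivariate normal log-density (naive oracle, solves per row)
oracle_mvn_loglik <- function(X, mu, Sigma) {
  Sinv <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  s <- 0
  for (i in seq_len(nrow(X))) {
    d <- X[i, ] - mu
    s <- s - 0.5 * (length(mu) * log(2 * pi) + ld + drop(d %*% Sinv %*% d))
  }
  as.numeric(s)
}

## least-squares slope with its standard error (brute-force RDR oracle)
slope_with_se <- function(y, x) {
  xc <- x - mean(x)
  b <- sum(xc * y) / sum(xc^2)
  r <- y - mean(y) - b * xc
  se <- sqrt(sum(r^2) / (length(y) - 2)) / sqrt(sum(xc^2))
  c(slope = b, se = se)
}

## Table-V-like generating scenario for the (beta_R = 0.75, rho_MM = 0.4)
## sensitivity cell, used in parameter-recovery tests
recovery_scenario <- function() {
  list(sens = sensitivity_setting(beta_R = 0.75, rho_MM = 0.4),
       params = me_params(
         J = 2, beta_Q = 0.49, beta_M = 11.66, sigma2_T = 0.37,
         sigma2_h = c(0.082, 0.053),
         sigma2_Q = c(0.18, 0.18), sigma2_R = c(0.23, 0.17),
         sigma2_M = c(253.98, 309.70),
         rho_QQ = 0.57, rho_RR = 0.32,
         rho_QR_same = c(0.15, 0.22), rho_QR_diff = c(0.10, 0.22),
         alpha_Q = c(5.98, 6.04), alpha_R = c(5.34, 5.52),
         alpha_M = c(53.0, 62.5)))
}
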