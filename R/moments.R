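#' Error-correlation matrix of the observed vector
#'
#' Builds the `3J x 3J` correlation matrix of the measurement error terms
#' in slot order `(Q_1..Q_J, R_1..R_J, M_1..M_J)`: within-instrument
#' blocks from `rho_QQ` / `rho_RR` / the fixed `rho_MM`, the
#' questionnaire-record block from `rho_QR` (same- and different-time
#' entries), and zeros between self-reports and the biomarker.
#'
#' @inheritParams validate_me_params
#' @return A `3J x 3J` correlation matrix with slot-label dimnames.
#' @export
error_correlation_matrix <- function(params, sens) {
  J <- params$J
  C <- diag(1, 3L * J)
  iQ <- seq_len(J); iR <- J + iQ; iM <- 2L * J + iQ
  C[iQ, iQ] <- params$rho_QQ
  C[iR, iR] <- params$rho_RR
  C[iQ, iR] <- params$rho_QR
  C[iR, iQ] <- t(params$rho_QR)
  MM <- matrix(sens$rho_MM, J, J); diag(MM) <- 1
  C[iM, iM] <- MM
  dimnames(C) <- list(slot_labels(J), slot_labels(J))
  C
}

error_covariance <- function(params, sens) {
  sd_all <- sqrt(c(params$sigma2_Q, params$sigma2_R, params$sigma2_M))
  C <- error_correlation_matrix(params, sens)
  C * tcrossprod(sd_all)
}

#' Implied moments of the observed measurement vector
#'
#' Computes the mean and covariance of
#' `(Q_1..Q_J, R_1..R_J, M_1..M_J)` conditional on covariates implied by
#' the measurement error model: the structural part
#' `beta_X beta_Y (sigma2_T + 1[j==k] sigma2_h[j])` plus the error
#' covariance.  Covariate contributions (the `gamma` terms) are excluded;
#' the mean holds the time-specific intercepts.
#'
#' @inheritParams validate_me_params
#' @param validate check parameter invariants first (set `FALSE` inside
#'   optimization loops where a failed Cholesky is handled by the caller).
#' @return An object of class `"implied_moments"`: list with `order`
#'   (slot labels), `mean` (length `3J`), `cov` (`3J x 3J`).
#' @examples
#' p <- me_params(J = 2, beta_Q = 0.5, beta_M = 30, sigma2_T = 0.2,
#'                sigma2_h = c(0.05, 0.05), sigma2_Q = c(0.3, 0.3),
#'                sigma2_R = c(0.4, 0.4), sigma2_M = c(100, 100))
#' m <- build_implied_moments(p, sensitivity_setting())
#' m$cov["Q1", "M1"]  # 0.5 * 30 * (0.2 + 0.05)
#' @export
build_implied_moments <- function(params, sens = sensitivity_setting(),
                                  validate = TRUE) {
  stopifnot(inherits(params, "me_params"))
  if (validate) validate_me_params(params, sens)
  J <- params$J
  betas <- c(rep(params$beta_Q, J), rep(sens$beta_R, J), rep(params$beta_M, J))
  tt <- rep.int(seq_len(J), 3L)
  same <- outer(tt, tt, "==")
  S <- tcrossprod(betas) * (params$sigma2_T + same * params$sigma2_h[tt])
  cov <- S + error_covariance(params, sens)
  dimnames(cov) <- list(slot_labels(J), slot_labels(J))
  mu <- c(params$alpha_Q, params$alpha_R, params$alpha_M)
  names(mu) <- slot_labels(J)
  structure(list(order = slot_labels(J), mean = mu, cov = cov),
            class = "implied_moments")
}

#' @export
print.implied_moments <- function(x, ...) {
  cat("Implied moments (conditional on covariates), slot order:",
      paste(x$order, collapse = ", "), "\n")
  cat("mean:\n"); print(round(x$mean, 4))
  cat("covariance:\n"); print(round(x$cov, 4))
  invisible(x)
}
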