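#' Sensitivity setting: the fixed, unidentified parameter pair
#'
#' The scaling bias of the food record on true intake (`beta_R`) and the
#' correlation between repeated surrogate-biomarker error terms (`rho_MM`)
#' are not identified by validation data containing a questionnaire, a food
#' record and a surrogate biomarker.  They are therefore *fixed*, not
#' estimated, and results are reported over a grid of plausible values
#' (see [sensitivity_grid()]).
#'
#' @param beta_R positive scalar; scaling of the food record on true intake.
#'   `beta_R = 1` is the conventional assumption that the record is
#'   unbiased up to additive error.
#' @param rho_MM scalar in `[0, 1)`; correlation between error terms of
#'   repeated biomarker measurements, conditional on true intake and
#'   covariates.  `rho_MM = 0` is the conventional independence assumption.
#' @return An object of class `"sensitivity_setting"`.
#' @examples
#' sensitivity_setting(beta_R = 0.75, rho_MM = 0.4)
#' @export
sensitivity_setting <- function(beta_R = 1, rho_MM = 0) {
  if (!is.numeric(beta_R) || length(beta_R) != 1L || !is.finite(beta_R) ||
      beta_R <= 0)
    stop("'beta_R' must be a single positive number", call. = FALSE)
  if (!is.numeric(rho_MM) || length(rho_MM) != 1L || !is.finite(rho_MM) ||
      rho_MM < 0 || rho_MM >= 1)
    stop("'rho_MM' must be a single number in [0, 1)", call. = FALSE)
  structure(list(beta_R = beta_R, rho_MM = rho_MM),
            class = "sensitivity_setting")
}

#' @export
print.sensitivity_setting <- function(x, ...) {
  cat(sprintf("Sensitivity setting: beta_R = %g (fixed), rho_MM = %g (fixed)\n",
              x$beta_R, x$rho_MM))
  invisible(x)
}

slot_labels <- function(J) {
  c(paste0("Q", seq_len(J)), paste0("R", seq_len(J)), paste0("M", seq_len(J)))
}

## normalize a correlation specification for a within-instrument block:
## scalar -> constant off-diagonal; matrix -> symmetrized with unit diagonal
as_corr_block <- function(x, J, what) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(J, J)))
      stop(sprintf("'%s' matrix must be %d x %d", what, J, J), call. = FALSE)
    m <- (x + t(x)) / 2
    diag(m) <- 1
  } else {
    if (length(x) != 1L && length(x) != J * (J - 1L) / 2L)
      stop(sprintf("'%s' must be a scalar, a %d x %d matrix, or the %d upper-triangular values",
                   what, J, J, J * (J - 1L) / 2L), call. = FALSE)
    m <- diag(1, J)
    m[upper.tri(m)] <- x
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  m
}

## rho_QR: full J x J matrix; [j, k] = corr(eps_Q at j, eps_R at k).
## Accepts same-time vector + (ordered) different-time values.
as_qr_block <- function(same, diff, J) {
  same <- rep_len(same, J)
  m <- diag(0, J)
  diag(m) <- same
  if (J > 1L) {
    off <- row(m) != col(m)
    if (is.matrix(diff)) {
      if (!all(dim(diff) == c(J, J)))
        stop("'rho_QR_diff' matrix must be J x J", call. = FALSE)
      m[off] <- diff[off]
    } else if (length(diff) == 1L) {
      m[off] <- diff
    } else if (J == 2L && length(diff) == 2L) {
      ## c(corr(eps_Q1, eps_R2), corr(eps_Q2, eps_R1))
      m[1, 2] <- diff[1]
      m[2, 1] <- diff[2]
    } else if (length(diff) == sum(off)) {
      m[off] <- diff
    } else {
      stop("'rho_QR_diff' has an unusable length", call. = FALSE)
    }
  }
  m
}

#' Parameters of the longitudinal measurement error model
#'
#' Container for all free parameters of the three-instrument longitudinal
#' measurement error model.  For individual `i` at time `j`, with latent
#' long-term intake `T_i` (between-person variance `sigma2_T` given
#' covariates) and time-specific intake `T_ij = T_i + h_ij`
#' (`var(h_ij) = sigma2_h[j]`), the observed measurements are
#' \deqn{Q_{ij} = \alpha_{Qj} + \beta_Q T_{ij} + \gamma_Q' Z_{Qij} + \epsilon_{Qij}}
#' \deqn{R_{ij} = \alpha_{Rj} + \beta_R T_{ij} + \epsilon_{Rij}}
#' \deqn{M_{ij} = \alpha_{Mj} + \beta_M T_{ij} + \gamma_M' Z_{Mij} + \epsilon_{Mij}}
#' with zero-mean normal errors of time-specific variance
#' `sigma2_Q[j]`, `sigma2_R[j]`, `sigma2_M[j]`.  Errors of the two
#' self-reported instruments may be correlated with each other and across
#' repeats (`rho_QQ`, `rho_RR`, `rho_QR_same`, `rho_QR_diff`); errors of
#' self-reports and biomarker are uncorrelated; repeated biomarker errors
#' have the fixed correlation `rho_MM` of the [sensitivity_setting()].
#' The food record has no covariate effects of its own (`gamma_R == 0`)
#' and `beta_R` is fixed; both are identifiability constraints.
#'
#' @param J number of time points (>= 1).
#' @param beta_Q,beta_M scalings of questionnaire and biomarker on true
#'   intake.  `beta_M` is in biomarker units per (analysis-scale) exposure
#'   unit.
#' @param sigma2_T between-person variance of long-term intake given
#'   covariates (> 0).
#' @param sigma2_h length-`J` within-person intake deviation variances
#'   (>= 0; 0 collapses to time-constant truth).
#' @param sigma2_Q,sigma2_R,sigma2_M length-`J` error variances (> 0).
#' @param rho_QQ,rho_RR correlations between errors in repeated
#'   questionnaires / records: scalar, upper-triangular values, or a
#'   `J x J` matrix.
#' @param rho_QR_same length-`J` error correlation between questionnaire
#'   and record at the same time point.
#' @param rho_QR_diff error correlation between questionnaire at `j` and
#'   record at `k != j`; scalar, a `J x J` matrix (off-diagonal used), or
#'   for `J = 2` the ordered pair `c(Q1-R2, Q2-R1)`.
#' @param alpha_Q,alpha_R,alpha_M length-`J` time-specific intercepts.
#' @param gamma_T,gamma_Q,gamma_M covariate coefficient vectors for the
#'   covariate blocks associated with true intake, questionnaire error and
#'   biomarker error.  The record coefficients are identically zero and
#'   have no slot.
#' @return An object of class `"me_params"`.
#' @seealso [build_implied_moments()], [rdr()], [fit_ml()]
#' @examples
#' p <- me_params(J = 2, beta_Q = 0.66, beta_M = 50, sigma2_T = 0.07,
#'                sigma2_h = c(0.014, 0.009), sigma2_Q = c(0.25, 0.25),
#'                sigma2_R = c(0.41, 0.34), sigma2_M = c(117, 181),
#'                rho_QQ = 0.65, rho_RR = 0.56,
#'                rho_QR_same = c(0.45, 0.51), rho_QR_diff = c(0.38, 0.44))
#' @export
me_params <- function(J,
                      beta_Q = 1, beta_M = 1,
                      sigma2_T = 1,
                      sigma2_h = rep(0, J),
                      sigma2_Q = rep(1, J),
                      sigma2_R = rep(1, J),
                      sigma2_M = rep(1, J),
                      rho_QQ = 0, rho_RR = 0,
                      rho_QR_same = rep(0, J), rho_QR_diff = 0,
                      alpha_Q = rep(0, J), alpha_R = rep(0, J),
                      alpha_M = rep(0, J),
                      gamma_T = numeric(0), gamma_Q = numeric(0),
                      gamma_M = numeric(0)) {
  J <- as.integer(J)
  if (J < 1L) stop("'J' must be >= 1", call. = FALSE)
  p <- structure(list(
    J = J,
    beta_Q = as.numeric(beta_Q), beta_M = as.numeric(beta_M),
    sigma2_T = as.numeric(sigma2_T),
    sigma2_h = rep_len(as.numeric(sigma2_h), J),
    sigma2_Q = rep_len(as.numeric(sigma2_Q), J),
    sigma2_R = rep_len(as.numeric(sigma2_R), J),
    sigma2_M = rep_len(as.numeric(sigma2_M), J),
    rho_QQ = as_corr_block(rho_QQ, J, "rho_QQ"),
    rho_RR = as_corr_block(rho_RR, J, "rho_RR"),
    rho_QR = as_qr_block(rho_QR_same, rho_QR_diff, J),
    alpha_Q = rep_len(as.numeric(alpha_Q), J),
    alpha_R = rep_len(as.numeric(alpha_R), J),
    alpha_M = rep_len(as.numeric(alpha_M), J),
    gamma_T = as.numeric(gamma_T),
    gamma_Q = as.numeric(gamma_Q),
    gamma_M = as.numeric(gamma_M)
  ), class = "me_params")
  p
}

#' Validate model parameters against a sensitivity setting
#'
#' Checks the parameter invariants: positive variances (`sigma2_h >= 0`
#' allowed), all stated correlations in (-1, 1), and positive definiteness
#' of the implied `3J x 3J` error-correlation matrix (with zero
#' self-report--biomarker correlations and `rho_MM` from `sens`).
#'
#' @param params an [me_params()] object.
#' @param sens a [sensitivity_setting()].
#' @return `TRUE` invisibly, or an error naming the offending entry.
#' @export
validate_me_params <- function(params, sens = sensitivity_setting()) {
  stopifnot(inherits(params, "me_params"), inherits(sens, "sensitivity_setting"))
  J <- params$J
  chk_var <- function(x, nm, zero_ok = FALSE) {
    bad <- if (zero_ok) x < 0 else x <= 0
    if (any(!is.finite(x)) || any(bad))
      stop(sprintf("invalid parameter: '%s' must be %s (got %s)", nm,
                   if (zero_ok) ">= 0" else "> 0",
                   paste(signif(x, 4), collapse = ", ")), call. = FALSE)
  }
  chk_var(params$sigma2_T, "sigma2_T")
  chk_var(params$sigma2_h, "sigma2_h", zero_ok = TRUE)
  chk_var(params$sigma2_Q, "sigma2_Q")
  chk_var(params$sigma2_R, "sigma2_R")
  chk_var(params$sigma2_M, "sigma2_M")
  if (!is.finite(params$beta_Q) || !is.finite(params$beta_M))
    stop("invalid parameter: scalings must be finite", call. = FALSE)
  rho_all <- c(params$rho_QQ[upper.tri(params$rho_QQ)],
               params$rho_RR[upper.tri(params$rho_RR)],
               params$rho_QR)
  if (any(!is.finite(rho_all)) || any(abs(rho_all) >= 1))
    stop("invalid parameter: every error correlation must lie in (-1, 1)",
         call. = FALSE)
  C <- error_correlation_matrix(params, sens)
  ev <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ev)) {
    lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf(paste0("invalid parameter: the %d x %d error-correlation ",
                        "matrix is not positive definite (smallest eigenvalue ",
                        "%.3g); reduce the magnitude of the rho_* entries"),
                 3L * J, 3L * J, min(lam)), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.me_params <- function(x, ...) {
  J <- x$J
  cat(sprintf("Measurement error model parameters (J = %d time points)\n", J))
  cat(sprintf("  scalings:   beta_Q = %.4g, beta_M = %.4g (beta_R fixed by sensitivity setting)\n",
              x$beta_Q, x$beta_M))
  cat(sprintf("  intake:     sigma2_T = %.4g, sigma2_h = %s\n",
              x$sigma2_T, paste(signif(x$sigma2_h, 4), collapse = ", ")))
  cat(sprintf("  error var:  Q: %s | R: %s | M: %s\n",
              paste(signif(x$sigma2_Q, 4), collapse = ", "),
              paste(signif(x$sigma2_R, 4), collapse = ", "),
              paste(signif(x$sigma2_M, 4), collapse = ", ")))
  if (J > 1L)
    cat(sprintf("  error corr: rho_QQ = %s, rho_RR = %s\n",
                paste(signif(x$rho_QQ[upper.tri(x$rho_QQ)], 3), collapse = ", "),
                paste(signif(x$rho_RR[upper.tri(x$rho_RR)], 3), collapse = ", ")))
  cat(sprintf("              rho_QR(same) = %s", paste(signif(diag(x$rho_QR), 3), collapse = ", ")))
  if (J > 1L) {
    off <- x$rho_QR[row(x$rho_QR) != col(x$rho_QR)]
    cat(sprintf(", rho_QR(diff) = %s", paste(signif(off, 3), collapse = ", ")))
  }
  cat("\n")
  for (g in c("gamma_T", "gamma_Q", "gamma_M"))
    if (length(x[[g]]))
      cat(sprintf("  %s: %s\n", g, paste(signif(x[[g]], 4), collapse = ", ")))
  invisible(x)
}

#' Serialize model parameters to a structured text configuration
#'
#' Parameters round-trip exactly (all fields, full double precision)
#' through a YAML document, so that a fitted or hand-specified model can
#' be stored alongside the data and re-loaded.
#'
#' @param params an [me_params()] object.
#' @param path file to write; if `NULL`, the YAML string is returned.
#' @return `path` invisibly (or the YAML string).
#' @export
write_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "me_params"))
  lst <- unclass(params)
  lst$rho_QQ <- as.vector(lst$rho_QQ)
  lst$rho_RR <- as.vector(lst$rho_RR)
  lst$rho_QR <- as.vector(lst$rho_QR)
  ## doubles are stored as %.17g strings: 17 significant digits are
  ## guaranteed to reproduce the IEEE double exactly on re-parse
  lst <- lapply(lst, function(v)
    if (is.double(v)) sprintf("%.17g", v) else v)
  txt <- yaml::as.yaml(lst)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read model parameters from a YAML configuration
#'
#' @param path file written by [write_params()] (or a YAML string
#'   containing the same fields).
#' @return An [me_params()] object.
#' @export
read_params <- function(path) {
  lst <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  J <- as.integer(lst$J)
  lst <- lapply(lst, function(v) if (is.character(v)) as.numeric(v) else v)
  mk <- function(v) matrix(as.numeric(v), J, J)
  me_params(J = J, beta_Q = lst$beta_Q, beta_M = lst$beta_M,
            sigma2_T = lst$sigma2_T, sigma2_h = lst$sigma2_h,
            sigma2_Q = lst$sigma2_Q, sigma2_R = lst$sigma2_R,
            sigma2_M = lst$sigma2_M,
            rho_QQ = mk(lst$rho_QQ), rho_RR = mk(lst$rho_RR),
            rho_QR_same = diag(mk(lst$rho_QR)), rho_QR_diff = mk(lst$rho_QR),
            alpha_Q = lst$alpha_Q, alpha_R = lst$alpha_R, alpha_M = lst$alpha_M,
            gamma_T = if (is.null(lst$gamma_T)) numeric(0) else lst$gamma_T,
            gamma_Q = if (is.null(lst$gamma_Q)) numeric(0) else lst$gamma_Q,
            gamma_M = if (is.null(lst$gamma_M)) numeric(0) else lst$gamma_M)
}

#' Realistic example parameters for a fruit-and-vegetable validation study
#'
#' A two-time-point parameter set of the magnitude seen in large dietary
#' validation studies of fruit and vegetable intake: questionnaire and
#' record on the log g/day scale, a plasma-concentration biomarker on its
#' natural scale (hence the large `beta_M` and biomarker error variances),
#' strong correlations between self-report errors, modest within-person
#' intake variation relative to between-person variation.  Used as the
#' default scenario of the simulator and throughout the package tests.
#'
#' The set is indexed by the sensitivity pair: the baseline corresponds to
#' `beta_R = 1, rho_MM = 0`; other `rho_MM` values select the matching
#' reallocation of variance between true intake and biomarker error, and
#' other `beta_R` values apply the exact scaling law (`beta_Q`, `beta_M`
#' multiplied by `beta_R`, intake variances divided by `beta_R^2`; error
#' variances and correlations unchanged).
#'
#' @param sens a [sensitivity_setting()]; `rho_MM` must be one of
#'   0, 0.2, 0.4.
#' @return An [me_params()] object (J = 2).
#' @export
fv_example_params <- function(sens = sensitivity_setting()) {
  stopifnot(inherits(sens, "sensitivity_setting"))
  tab <- list(
    `0` = list(beta_Q = 0.66, beta_M = 50, sigma2_T = 0.07,
               sigma2_h = c(0.014, 0.009),
               sigma2_Q = c(0.25, 0.25), sigma2_R = c(0.41, 0.34),
               sigma2_M = c(117, 181),
               rho_QQ = 0.65, rho_RR = 0.56,
               rho_QR_same = c(0.45, 0.51), rho_QR_diff = c(0.38, 0.44)),
    `0.2` = list(beta_Q = 0.66, beta_M = 38.2, sigma2_T = 0.09,
                 sigma2_h = c(0.019, 0.012),
                 sigma2_Q = c(0.24, 0.24), sigma2_R = c(0.39, 0.32),
                 sigma2_M = c(164, 225),
                 rho_QQ = 0.64, rho_RR = 0.54,
                 rho_QR_same = c(0.43, 0.48), rho_QR_diff = c(0.36, 0.42)),
    `0.4` = list(beta_Q = 0.66, beta_M = 15.6, sigma2_T = 0.21,
                 sigma2_h = c(0.046, 0.030),
                 sigma2_Q = c(0.18, 0.18), sigma2_R = c(0.23, 0.17),
                 sigma2_M = c(254, 310),
                 rho_QQ = 0.57, rho_RR = 0.32,
                 rho_QR_same = c(0.15, 0.22), rho_QR_diff = c(0.10, 0.22))
  )
  key <- as.character(sens$rho_MM)
  if (!key %in% names(tab))
    stop("fv_example_params is tabulated for rho_MM in {0, 0.2, 0.4}",
         call. = FALSE)
  v <- tab[[key]]
  c_ <- sens$beta_R  # exact scaling law relative to the beta_R = 1 entry
  me_params(J = 2,
            beta_Q = v$beta_Q * c_, beta_M = v$beta_M * c_,
            sigma2_T = v$sigma2_T / c_^2, sigma2_h = v$sigma2_h / c_^2,
            sigma2_Q = v$sigma2_Q, sigma2_R = v$sigma2_R,
            sigma2_M = v$sigma2_M,
            rho_QQ = v$rho_QQ, rho_RR = v$rho_RR,
            rho_QR_same = v$rho_QR_same, rho_QR_diff = v$rho_QR_diff,
            alpha_Q = c(5.98, 6.04), alpha_R = c(5.34, 5.52),
            alpha_M = c(53.0, 62.5))
}
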