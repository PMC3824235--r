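inst_index <- function(instrument, j, J) {
  k <- match(instrument, c("Q", "R", "M"))
  if (is.na(k)) stop("'instrument' must be one of \"Q\", \"R\", \"M\"",
                     call. = FALSE)
  if (j < 1L || j > J) stop("time index 'j' out of range", call. = FALSE)
  (k - 1L) * J + j
}

inst_beta <- function(params, sens, instrument) {
  switch(instrument, Q = params$beta_Q, R = sens$beta_R, M = params$beta_M)
}

#' Regression dilution ratio for a dietary instrument
#'
#' The regression dilution ratio (RDR) `lambda` is the multiplicative bias
#' in an estimated diet--disease association when the error-prone
#' measurement `X_ij` replaces true intake; regression calibration divides
#' the observed log odds/hazard ratio by it.  Conditional on the
#' true-intake covariates, the closed forms under the model are
#' \deqn{\lambda_{lt} = \beta_X \sigma^2_T / var(X_{ij} | Z)}
#' for long-term intake `T_i` as the exposure, and
#' \deqn{\lambda_{ts} = \beta_X (\sigma^2_T + \sigma^2_{hj}) / var(X_{ij} | Z)}
#' for time-specific intake `T_ij`.  RDRs may exceed 1 (amplification).
#'
#' @inheritParams validate_me_params
#' @param instrument `"Q"` (questionnaire) or `"R"` (food record); the
#'   surrogate biomarker is not used as a main exposure measurement.
#' @param j time index in `1..J`.
#' @param exposure `"longterm"` (exposure `T_i`) or `"timespecific"`
#'   (exposure `T_ij`).
#' @return The scalar RDR.
#' @seealso [corr_with_true()], [derived_quantities()]
#' @examples
#' # classical measurement error: lambda = sigma2_T / (sigma2_T + sigma2_eps)
#' p <- me_params(J = 1, beta_Q = 1, sigma2_T = 1, sigma2_Q = 1)
#' rdr(p, sensitivity_setting(), "Q", 1)  # 0.5
#' @export
rdr <- function(params, sens = sensitivity_setting(), instrument = "Q",
                j = 1L, exposure = c("longterm", "timespecific")) {
  exposure <- match.arg(exposure)
  instrument <- match.arg(instrument, c("Q", "R"))
  validate_me_params(params, sens)
  b <- inst_beta(params, sens, instrument)
  if (b == 0) stop("degenerate instrument: scaling beta is zero, the RDR is undefined",
                   call. = FALSE)
  mom <- build_implied_moments(params, sens, validate = FALSE)
  v <- mom$cov[inst_index(instrument, j, params$J),
               inst_index(instrument, j, params$J)]
  num <- if (exposure == "longterm") params$sigma2_T else
    params$sigma2_T + params$sigma2_h[j]
  b * num / v
}

#' Correlation of a dietary measurement with true intake
#'
#' Conditional (on covariates) correlation between the measurement
#' `X_ij` and either long-term intake `T_i` or time-specific intake
#' `T_ij`.  These correlations determine the power of a study to detect
#' diet--outcome associations with the instrument, and -- unlike the RDRs
#' -- do not depend on the unidentified record scaling `beta_R`.
#'
#' @inheritParams rdr
#' @param instrument `"Q"`, `"R"` or `"M"`.
#' @return The scalar correlation (in `[-1, 1]`).
#' @export
corr_with_true <- function(params, sens = sensitivity_setting(),
                           instrument = "Q", j = 1L,
                           exposure = c("longterm", "timespecific")) {
  exposure <- match.arg(exposure)
  instrument <- match.arg(instrument, c("Q", "R", "M"))
  validate_me_params(params, sens)
  mom <- build_implied_moments(params, sens, validate = FALSE)
  v <- mom$cov[inst_index(instrument, j, params$J),
               inst_index(instrument, j, params$J)]
  if (v <= 0) stop("degenerate instrument: zero variance", call. = FALSE)
  b <- inst_beta(params, sens, instrument)
  s2 <- if (exposure == "longterm") params$sigma2_T else
    params$sigma2_T + params$sigma2_h[j]
  ## cov(X, T) = b * s2; sd(T) = sqrt(s2)
  b * sqrt(s2) / sqrt(v)
}

#' Back-transformed RDR on the original exposure scale
#'
#' The model is fitted on the analysis scale (self-reports logged).  When
#' the diet--disease model uses untransformed intake, the RDR on the
#' original scale is the slope of true exposed-scale intake on the
#' exposed-scale measurement.  This is estimated by Monte Carlo: simulate
#' `(T, X)` from the fitted bivariate normal on the analysis scale,
#' exponentiate both, and return the least-squares slope of `exp(T)` on
#' `exp(X)`.
#'
#' @inheritParams rdr
#' @param n_mc number of Monte Carlo draws (>= 1e4).
#' @param seed integer seed; the estimate is reproducible given the seed.
#' @return Scalar slope estimate with attribute `"mc_se"` (the
#'   regression standard error of the slope).
#' @export
backtransform_rdr <- function(params, sens = sensitivity_setting(),
                              instrument = "Q", j = 1L,
                              exposure = c("longterm", "timespecific"),
                              n_mc = 1e5, seed = 1L) {
  exposure <- match.arg(exposure)
  instrument <- match.arg(instrument, c("Q", "R"))
  validate_me_params(params, sens)
  if (n_mc < 1e4) stop("'n_mc' must be at least 1e4", call. = FALSE)
  mom <- build_implied_moments(params, sens, validate = FALSE)
  ix <- inst_index(instrument, j, params$J)
  s2 <- if (exposure == "longterm") params$sigma2_T else
    params$sigma2_T + params$sigma2_h[j]
  b <- inst_beta(params, sens, instrument)
  ## bivariate normal for (T, X): var(T) = s2, cov = b * s2
  S <- matrix(c(s2, b * s2, b * s2, mom$cov[ix, ix]), 2, 2)
  mu <- c(0, mom$mean[ix])
  L <- chol(S)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(2 * n_mc), n_mc, 2) %*% L
  eT <- exp(Z[, 1] + mu[1])
  eX <- exp(Z[, 2] + mu[2])
  ## least-squares slope with a heteroskedasticity-robust (sandwich) MC
  ## standard error: the exponentiated variables are heavy-tailed and the
  ## homoskedastic slope SE badly understates the Monte-Carlo noise
  xc <- eX - mean(eX)
  slope <- sum(xc * eT) / sum(xc^2)
  resid <- eT - mean(eT) - slope * xc
  structure(slope, mc_se = sqrt(sum(resid^2 * xc^2)) / sum(xc^2))
}

#' All derived quantities of a model (RDRs and correlations)
#'
#' Tabulates, for every instrument and time point, the long-term and
#' time-specific RDRs (questionnaire and record) and correlations with
#' true intake (all three instruments).  When called on a fitted model
#' ([fit_ml()] result), delta-method standard errors are attached; see
#' [standard_errors()] for the bootstrap alternative.
#'
#' @param object an [me_params()] object or an `"me_fit"` result.
#' @param sens a [sensitivity_setting()]; ignored (taken from the fit)
#'   when `object` is a fit.
#' @return A data frame with columns `quantity` (`"rdr"`/`"corr"`),
#'   `instrument`, `time`, `exposure`, `estimate` and (for fits) `se`.
#' @export
derived_quantities <- function(object, sens = sensitivity_setting()) {
  if (inherits(object, "me_fit"))
    return(derived_quantities_fit(object))
  params <- object
  J <- params$J
  grid_r <- expand.grid(instrument = c("Q", "R"), time = seq_len(J),
                        exposure = c("longterm", "timespecific"),
                        stringsAsFactors = FALSE)
  grid_c <- expand.grid(instrument = c("Q", "R", "M"), time = seq_len(J),
                        exposure = c("longterm", "timespecific"),
                        stringsAsFactors = FALSE)
  out <- rbind(
    data.frame(quantity = "rdr", grid_r,
               estimate = mapply(function(i, j, e)
                 rdr(params, sens, i, j, e),
                 grid_r$instrument, grid_r$time, grid_r$exposure)),
    data.frame(quantity = "corr", grid_c,
               estimate = mapply(function(i, j, e)
                 corr_with_true(params, sens, i, j, e),
                 grid_c$instrument, grid_c$time, grid_c$exposure)))
  rownames(out) <- NULL
  out
}
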