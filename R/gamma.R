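## long-format stack of one instrument with a covariate block
stack_long <- function(data, X, block) {
  J <- data$J
  rows <- list()
  for (j in seq_len(J)) {
    y <- data[[X]][, j]
    obs <- !is.na(y)
    if (!any(obs)) next
    Z <- block[[j]][obs, , drop = FALSE]
    rows[[j]] <- data.frame(id = data$id[obs], time = j, y = y[obs],
                            Z, check.names = FALSE)
  }
  do.call(rbind, rows)
}

#' Estimate covariate effects on true intake
#'
#' The true-intake covariate coefficients are recovered from a
#' random-intercept linear mixed model (ML) of the food record on the
#' true-intake covariates, with the fitted slopes divided by the fixed
#' record scaling `beta_R` (the record has no reporting covariates of its
#' own, so its regression on `Z_T` estimates `beta_R * gamma_T`).
#' Standard errors are scaled by the same factor.
#'
#' @param data an [me_data()] object on the analysis scale, *not*
#'   residualized, with a nonempty `Z_T` block and some observed records.
#' @param sens a [sensitivity_setting()] supplying `beta_R`.
#' @return Data frame with `term`, `estimate`, `se`.
#' @export
estimate_gamma_T <- function(data, sens = sensitivity_setting()) {
  stopifnot(inherits(data, "me_data"))
  if (isTRUE(attr(data, "residualized")))
    stop("estimate_gamma_T needs the raw (non-residualized) measurements",
         call. = FALSE)
  if (ncol(data$Z_T[[1]]) == 0L) stop("no true-intake covariates (Z_T empty)",
                                      call. = FALSE)
  long <- stack_long(data, "R", data$Z_T)
  if (is.null(long) || !nrow(long)) stop("no observed food records", call. = FALSE)
  zcols <- colnames(data$Z_T[[1]])
  tab <- mixed_coefs(long, zcols)
  tab$estimate <- tab$estimate / sens$beta_R
  tab$se <- tab$se / sens$beta_R
  tab
}

#' Estimate covariate effects on questionnaire or biomarker error
#'
#' The secondary covariate effects are recovered from a random-intercept
#' mixed model on a constructed response that removes the true-intake
#' signal using the record: `Q_ij - beta_Q R_ij / beta_R` for the
#' questionnaire (`which = "Q"`, covariates `Z_Q`), or
#' `M_ij - beta_M R_ij / beta_R` for the biomarker (`which = "M"`,
#' covariates `Z_M`).  The scalings are replaced by their ML estimates
#' from `fit`; reported standard errors ignore the uncertainty in those
#' estimates.
#'
#' @param data an [me_data()] object, not residualized; rows used are
#'   those with both the instrument and the record observed.
#' @param fit a converged `"me_fit"` supplying `beta_Q` / `beta_M` and
#'   the sensitivity setting.
#' @param which `"Q"` or `"M"`.
#' @return Data frame with `term`, `estimate`, `se`.
#' @export
estimate_gamma_secondary <- function(data, fit, which = c("Q", "M")) {
  which <- match.arg(which)
  stopifnot(inherits(data, "me_data"), inherits(fit, "me_fit"))
  if (!fit$converged) stop("'fit' did not converge", call. = FALSE)
  block <- if (which == "Q") data$Z_Q else data$Z_M
  if (ncol(block[[1]]) == 0L)
    stop(sprintf("no covariates in Z_%s", which), call. = FALSE)
  b <- if (which == "Q") fit$params$beta_Q else fit$params$beta_M
  ratio <- b / fit$sens$beta_R
  d2 <- data
  d2[[which]] <- data[[which]] - ratio * data$R  # NA wherever either is missing
  long <- stack_long(d2, which, block)
  if (is.null(long) || !nrow(long))
    stop(sprintf("no rows with both %s and R observed", which), call. = FALSE)
  mixed_coefs(long, colnames(block[[1]]))
}

## random-intercept ML fit with OLS fallback when the grouping carries no
## information (single measurement per individual, or singular fit)
mixed_coefs <- function(long, zcols) {
  fml <- stats::as.formula(paste("y ~",
                                 paste(sprintf("`%s`", zcols), collapse = " + "),
                                 "+ (1 | id)"))
  sm_mm <- tryCatch(
    suppressWarnings(suppressMessages({
      fit <- lme4::lmer(fml, data = long, REML = FALSE,
                        control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                    check.nobs.vs.nRE = "ignore"))
      stats::coef(summary(fit))
    })),
    error = function(e) NULL)
  if (is.null(sm_mm)) {
    warning("mixed model failed; falling back to ordinary least squares")
    fml2 <- stats::as.formula(paste("y ~",
                                    paste(sprintf("`%s`", zcols), collapse = " + ")))
    f <- stats::lm(fml2, data = long)
    sm <- summary(f)$coefficients
    sel <- rownames(sm) != "(Intercept)"
    return(data.frame(term = gsub("`", "", rownames(sm)[sel]),
                      estimate = sm[sel, 1], se = sm[sel, 2],
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  sel <- rownames(sm_mm) != "(Intercept)"
  data.frame(term = gsub("`", "", rownames(sm_mm)[sel]),
             estimate = sm_mm[sel, "Estimate"], se = sm_mm[sel, "Std. Error"],
             stringsAsFactors = FALSE, row.names = NULL)
}
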