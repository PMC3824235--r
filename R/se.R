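## derived quantities with delta-method SEs propagated from the
## observed-information vcov of the transformed free parameters
derived_quantities_fit <- function(fit) {
  base <- derived_quantities(fit$params, fit$sens)
  if (is.null(fit$vcov)) {
    base$se <- NA_real_
    return(base)
  }
  gfun <- function(theta) {
    p <- unpack_theta(theta, fit$map, fit$template)
    derived_quantities(p, fit$sens)$estimate
  }
  th <- fit$theta
  K <- length(th)
  g0 <- base$estimate
  Jac <- matrix(NA_real_, length(g0), K)
  for (k in seq_len(K)) {
    h <- 1e-5 * max(1, abs(th[k]))
    tp <- th; tp[k] <- th[k] + h
    tm <- th; tm[k] <- th[k] - h
    Jac[, k] <- (gfun(tp) - gfun(tm)) / (2 * h)
  }
  v <- rowSums((Jac %*% fit$vcov) * Jac)
  base$se <- sqrt(pmax(v, 0))
  base
}

#' Standard errors for parameters and derived quantities
#'
#' Two methods are offered (the choice is an implementation decision of
#' this package): `"delta"` propagates the inverse observed information
#' through the transformed-parameter maps and the closed-form RDR /
#' correlation expressions by numerical Jacobian; `"bootstrap"` resamples
#' individuals nonparametrically, refits each replicate (warm-started at
#' the point estimate) and reports the replicate standard deviation.
#' Parameters fixed by the sensitivity setting (`beta_R`, `rho_MM`) are
#' reported with a standard error of exactly 0.
#'
#' @param fit an `"me_fit"` result (converged).
#' @param data the dataset the model was fitted to (required for the
#'   bootstrap).
#' @param method `"delta"` or `"bootstrap"`.
#' @param B bootstrap replicates.
#' @param seed seed for the bootstrap resampling.
#' @return List with data frames `params` (`parameter`, `estimate`, `se`)
#'   and `derived` (as [derived_quantities()] plus `se`), and `method`.
#' @export
standard_errors <- function(fit, data = NULL,
                            method = c("delta", "bootstrap"), B = 200L,
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "me_fit"))
  if (!fit$converged)
    warning("fit did not converge; standard errors may be meaningless")
  if (method == "delta" && is.null(fit$vcov)) {
    if (is.null(data))
      stop("observed information unavailable and no data supplied for bootstrap",
           call. = FALSE)
    warning("observed information unavailable; falling back to bootstrap")
    method <- "bootstrap"
  }

  fixed_rows <- data.frame(
    parameter = c("beta_R", "rho_MM"),
    estimate = c(fit$sens$beta_R, fit$sens$rho_MM),
    se = c(0, 0), stringsAsFactors = FALSE)

  if (method == "delta") {
    par_tab <- natural_se(fit)
    der <- derived_quantities_fit(fit)
  } else {
    if (is.null(data)) stop("'data' is required for the bootstrap", call. = FALSE)
    free <- fit$map[fit$map$free, , drop = FALSE]
    boot <- with_seed(as.integer(seed), {
      lapply(seq_len(B), function(b) {
        idx <- sample.int(data$n, data$n, replace = TRUE)
        db <- subset_me_data(data, idx)
        db$id <- seq_len(db$n)
        fb <- tryCatch(
          fit_ml(db, fit$sens, constraints = fit$constraints,
                 intercepts = fit$intercepts, start = fit$params,
                 compute_vcov = FALSE),
          error = function(e) NULL)
        if (is.null(fb) || !fb$converged) return(NULL)
        list(par = vapply(seq_len(nrow(free)), function(r)
               param_get(fb$params, free[r, ]), numeric(1)),
             der = derived_quantities(fb$params, fb$sens)$estimate)
      })
    })
    boot <- boot[!vapply(boot, is.null, logical(1))]
    if (length(boot) < 0.5 * B)
      warning(sprintf("only %d of %d bootstrap replicates converged",
                      length(boot), B))
    pmat <- do.call(rbind, lapply(boot, `[[`, "par"))
    dmat <- do.call(rbind, lapply(boot, `[[`, "der"))
    par_tab <- data.frame(parameter = free$name,
                          estimate = vapply(seq_len(nrow(free)), function(r)
                            param_get(fit$params, free[r, ]), numeric(1)),
                          se = apply(pmat, 2L, stats::sd),
                          stringsAsFactors = FALSE)
    der <- derived_quantities(fit$params, fit$sens)
    der$se <- apply(dmat, 2L, stats::sd)
  }
  list(params = rbind(par_tab, fixed_rows), derived = der, method = method)
}
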