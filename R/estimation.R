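## ---- free-parameter map -------------------------------------------------
## The optimizer works on an unconstrained vector theta: log for variances,
## atanh (Fisher z) for correlations, identity for scalings and intercepts.
## Joint positive definiteness of the implied covariance cannot be
## guaranteed by box constraints, so every likelihood evaluation verifies
## it and returns a -Inf sentinel on failure.

param_map <- function(J, constraints = list(), intercepts = "zero",
                      design = NULL) {
  ent <- function(name, family, i = NA_integer_, j = NA_integer_, transform) {
    data.frame(name = name, family = family, i = i, j = j,
               transform = transform, stringsAsFactors = FALSE)
  }
  rows <- list(
    ent("beta_Q", "beta_Q", transform = "id"),
    ent("beta_M", "beta_M", transform = "id"),
    ent("sigma2_T", "sigma2_T", transform = "log"))
  for (j in seq_len(J))
    rows <- c(rows, list(ent(paste0("sigma2_h", j), "sigma2_h", i = j,
                             transform = "log")))
  for (fam in c("sigma2_Q", "sigma2_R", "sigma2_M"))
    for (j in seq_len(J))
      rows <- c(rows, list(ent(paste0(fam, j), fam, i = j, transform = "log")))
  if (J > 1L) {
    for (fam in c("rho_QQ", "rho_RR"))
      for (j in seq_len(J - 1L)) for (k in (j + 1L):J)
        rows <- c(rows, list(ent(sprintf("%s_%d%d", fam, j, k), fam,
                                 i = j, j = k, transform = "atanh")))
  }
  for (j in seq_len(J))
    rows <- c(rows, list(ent(paste0("rho_QR_same", j), "rho_QR_same", i = j,
                             transform = "atanh")))
  if (J > 1L)
    for (j in seq_len(J)) for (k in seq_len(J)) if (j != k)
      rows <- c(rows, list(ent(sprintf("rho_QR_diff_%d%d", j, k),
                               "rho_QR_diff", i = j, j = k,
                               transform = "atanh")))
  for (fam in c("alpha_Q", "alpha_R", "alpha_M"))
    for (j in seq_len(J))
      rows <- c(rows, list(ent(paste0(fam, j), fam, i = j, transform = "id")))
  map <- do.call(rbind, rows)

  ## single time point: within-person deviation not separable from sigma2_T
  if (J == 1L && !"sigma2_h" %in% names(constraints))
    constraints$sigma2_h <- 0

  map$free <- TRUE
  map$fixed_value <- NA_real_
  if (intercepts == "zero")
    for (fam in c("alpha_Q", "alpha_R", "alpha_M"))
      if (!fam %in% names(constraints)) constraints[[fam]] <- 0
  for (fam in names(constraints)) {
    sel <- map$family == fam
    if (!any(sel)) next
    map$free[sel] <- FALSE
    map$fixed_value[sel] <- rep_len(as.numeric(constraints[[fam]]), sum(sel))
  }

  ## slots with no observations: pin their parameters at harmless values
  if (!is.null(design)) {
    absent <- list(Q = setdiff(seq_len(J), design$Q),
                   R = setdiff(seq_len(J), design$R),
                   M = setdiff(seq_len(J), design$M))
    pin <- function(sel, value) {
      sel <- sel & map$free
      map$free[sel] <<- FALSE
      map$fixed_value[sel] <<- value
    }
    for (X in c("Q", "R", "M")) for (j in absent[[X]]) {
      pin(map$family == paste0("sigma2_", X) & map$i == j, 1)
      pin(map$family == paste0("alpha_", X) & map$i == j, 0)
      pin(map$family %in% paste0("rho_", c("QQ", "RR")) &
            substr(map$family, 5, 5) == X & (map$i == j | map$j == j), 0)
      if (X == "Q") pin(grepl("^rho_QR", map$family) & map$i == j, 0)
      if (X == "R") pin(map$family == "rho_QR_same" & map$i == j, 0)
      if (X == "R") pin(map$family == "rho_QR_diff" & map$j == j, 0)
    }
    if (!length(design$Q)) pin(map$family == "beta_Q", 0)
    if (!length(design$M)) pin(map$family == "beta_M", 0)
  }
  map
}

param_get <- function(params, row) {
  switch(row$family,
    beta_Q = params$beta_Q, beta_M = params$beta_M,
    sigma2_T = params$sigma2_T,
    sigma2_h = params$sigma2_h[row$i],
    sigma2_Q = params$sigma2_Q[row$i],
    sigma2_R = params$sigma2_R[row$i],
    sigma2_M = params$sigma2_M[row$i],
    rho_QQ = params$rho_QQ[row$i, row$j],
    rho_RR = params$rho_RR[row$i, row$j],
    rho_QR_same = params$rho_QR[row$i, row$i],
    rho_QR_diff = params$rho_QR[row$i, row$j],
    alpha_Q = params$alpha_Q[row$i],
    alpha_R = params$alpha_R[row$i],
    alpha_M = params$alpha_M[row$i])
}

param_set <- function(params, row, value) {
  switch(row$family,
    beta_Q = params$beta_Q <- value,
    beta_M = params$beta_M <- value,
    sigma2_T = params$sigma2_T <- value,
    sigma2_h = params$sigma2_h[row$i] <- value,
    sigma2_Q = params$sigma2_Q[row$i] <- value,
    sigma2_R = params$sigma2_R[row$i] <- value,
    sigma2_M = params$sigma2_M[row$i] <- value,
    rho_QQ = params$rho_QQ[row$i, row$j] <- params$rho_QQ[row$j, row$i] <- value,
    rho_RR = params$rho_RR[row$i, row$j] <- params$rho_RR[row$j, row$i] <- value,
    rho_QR_same = params$rho_QR[row$i, row$i] <- value,
    rho_QR_diff = params$rho_QR[row$i, row$j] <- value,
    alpha_Q = params$alpha_Q[row$i] <- value,
    alpha_R = params$alpha_R[row$i] <- value,
    alpha_M = params$alpha_M[row$i] <- value)
  params
}

to_theta <- function(x, transform) {
  switch(transform, id = x,
         log = log(pmax(x, 1e-12)),
         atanh = atanh(pmin(pmax(x, -0.999), 0.999)))
}
from_theta <- function(x, transform) {
  switch(transform, id = x, log = exp(x), atanh = tanh(x))
}

pack_params <- function(params, map) {
  free <- map[map$free, , drop = FALSE]
  th <- vapply(seq_len(nrow(free)), function(r)
    to_theta(param_get(params, free[r, ]), free$transform[r]), numeric(1))
  names(th) <- free$name
  th
}

unpack_theta <- function(theta, map, template) {
  p <- template
  free <- which(map$free)
  for (r in seq_along(free)) {
    row <- map[free[r], ]
    p <- param_set(p, row, unname(from_theta(theta[r], row$transform)))
  }
  fixed <- which(!map$free)
  for (r in fixed) p <- param_set(p, map[r, ], map$fixed_value[r])
  p
}

## ---- residual covariate adjustment --------------------------------------

#' Residualize measurements on their covariates
#'
#' First step of the two-step fitting procedure: each measurement column
#' `X_ij` is replaced by the residual of an ordinary least-squares
#' regression of `X_ij` on the concatenation of the instrument's own
#' covariates and the true-intake covariates (`Z_X[, j]`, `Z_T[, j]`),
#' fitted separately per instrument and time point.  The residuals then
#' enter the likelihood with the covariate terms omitted and intercepts
#' fixed at zero.  Regression coefficients are retained for recovering
#' covariate effects later.
#'
#' @param data an [me_data()] object on the analysis scale.
#' @return The residualized dataset (attribute `residualized = TRUE`;
#'   per-column fits stored in attribute `residual_fits`).
#' @export
residualize <- function(data) {
  stopifnot(inherits(data, "me_data"))
  fits <- list()
  for (X in c("Q", "R", "M")) {
    ZX <- switch(X, Q = data$Z_Q, R = NULL, M = data$Z_M)  # record: gamma_R = 0
    for (j in seq_len(data$J)) {
      y <- data[[X]][, j]
      obs <- !is.na(y)
      if (!any(obs)) next
      D <- cbind(`(Intercept)` = 1,
                 if (!is.null(ZX)) ZX[[j]],
                 data$Z_T[[j]])
      if (anyNA(D[obs, ]))
        stop(sprintf("covariates missing where %s_%d is observed", X, j),
             call. = FALSE)
      qr_ <- qr(D[obs, , drop = FALSE])
      if (qr_$rank < ncol(D)) {
        drop_cols <- colnames(D)[qr_$pivot[(qr_$rank + 1L):ncol(D)]]
        stop(sprintf("rank-deficient covariate design for %s_%d; collinear column(s): %s",
                     X, j, paste(drop_cols, collapse = ", ")), call. = FALSE)
      }
      if (sum(obs) < ncol(D) + 2L)
        stop(sprintf("too few observations of %s_%d to residualize", X, j),
             call. = FALSE)
      cf <- qr.coef(qr_, y[obs])
      data[[X]][obs, j] <- y[obs] - drop(D[obs, , drop = FALSE] %*% cf)
      fits[[paste0(X, j)]] <- cf
    }
  }
  attr(data, "residualized") <- TRUE
  attr(data, "residual_fits") <- fits
  data
}

## ---- likelihood ---------------------------------------------------------

## per-pattern sufficient statistics: uncentered cross-products, so that
## the log-likelihood is an O(patterns x (3J)^2) function of the
## parameters regardless of n
make_pattern_stats <- function(data) {
  obs <- obs_matrix(data)
  pats <- group_patterns(data)
  lapply(pats, function(p) {
    X <- obs[p$idx, p$mask, drop = FALSE]
    list(mask = p$mask, n = p$n, s = colSums(X), CP = crossprod(X))
  })
}

loglik_stats <- function(params, sens, pstats) {
  mom <- tryCatch(build_implied_moments(params, sens, validate = FALSE),
                  error = function(e) NULL)
  if (is.null(mom)) return(-Inf)
  ll <- 0
  for (p in pstats) {
    mu <- mom$mean[p$mask]
    S <- mom$cov[p$mask, p$mask, drop = FALSE]
    L <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(L)) return(-Inf)
    k <- length(mu)
    Sinv <- chol2inv(L)
    M2 <- p$CP - tcrossprod(p$s, mu) - tcrossprod(mu, p$s) +
      p$n * tcrossprod(mu)
    ll <- ll - 0.5 * (p$n * k * log(2 * pi) + 2 * p$n * sum(log(diag(L))) +
                        sum(Sinv * M2))
  }
  ll
}

#' Full-cohort observed-data log-likelihood
#'
#' Sum over individuals of the marginal multivariate-normal log-density
#' of the observed subvector of `(Q, R, M)` measurements, using the
#' pattern-specific submatrix of the covariance implied by the model.
#' All individuals with at least one measurement contribute, which is
#' valid and efficient when measurements are missing at random.  A
#' parameter set whose implied covariance is not positive definite
#' returns `-Inf` (optimizer-safe) rather than failing.
#'
#' @inheritParams validate_me_params
#' @param data an [me_data()] object (residualized, or raw with the
#'   intercepts `alpha_*` carried in `params`).
#' @return Scalar log-likelihood.
#' @export
loglik <- function(params, sens, data) {
  stopifnot(inherits(data, "me_data"))
  loglik_stats(params, sens, make_pattern_stats(data))
}

## ---- starting values ----------------------------------------------------

## moment-based starting values from pairwise-complete sample moments;
## neutral defaults wherever the moment equations cannot be inverted
moment_start <- function(data, sens, constraints = list()) {
  J <- data$J
  obs <- obs_matrix(data)
  C <- suppressWarnings(stats::cov(obs, use = "pairwise.complete.obs"))
  mns <- colMeans(obs, na.rm = TRUE)
  iQ <- seq_len(J); iR <- J + iQ; iM <- 2L * J + iQ
  bR <- sens$beta_R

  neutral <- function() {
    vR <- C[iR[1], iR[1]]; vM <- C[iM[1], iM[1]]
    if (!is.finite(vR) || vR <= 0) vR <- 1
    if (!is.finite(vM) || vM <= 0) vM <- 1
    me_params(J, beta_Q = 1, beta_M = sqrt(vM / vR),
              sigma2_T = 0.5 * vR / bR^2,
              sigma2_h = rep(0.05 * vR / bR^2, J),
              sigma2_Q = 0.5 * pmax(diag(C)[iQ], 1e-3),
              sigma2_R = 0.5 * pmax(diag(C)[iR], 1e-3),
              sigma2_M = 0.5 * pmax(diag(C)[iM], 1e-3),
              rho_QQ = 0.3, rho_RR = 0.3,
              rho_QR_same = rep(0.3, J), rho_QR_diff = 0.2,
              alpha_Q = mns[iQ], alpha_R = mns[iR], alpha_M = mns[iM])
  }
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  p <- tryCatch({
    if (J >= 2L) {
      offd <- function(ii, jj) {
        m <- C[ii, jj, drop = FALSE]
        mean(m[row(m) != col(m)])
      }
      a_R <- offd(iR, iM) / bR            # beta_M * sigma2_T
      a_Q <- offd(iQ, iM)                 # beta_Q * beta_M * sigma2_T
      mm <- C[iM, iM]
      cMM <- mean(mm[upper.tri(mm)])
      s2M <- 0.5 * diag(C)[iM]
      beta_M <- sigma2_T <- NA
      for (it in 1:4) {
        b <- cMM - sens$rho_MM * mean(sqrt(tcrossprod(s2M))[upper.tri(mm)])
        if (!is.finite(b) || b <= 0 || a_R <= 0) stop("moment inversion failed")
        beta_M <- b / a_R
        sigma2_T <- a_R^2 / b
        s2h <- clip(diag(C[iR, iM, drop = FALSE]) / (bR * beta_M) - sigma2_T,
                    1e-4 * sigma2_T, 10 * sigma2_T)
        s2M <- clip(diag(C)[iM] - beta_M^2 * (sigma2_T + s2h),
                    0.05 * diag(C)[iM], Inf)
      }
      beta_Q <- a_Q / (beta_M * sigma2_T)
      s2Q <- clip(diag(C)[iQ] - beta_Q^2 * (sigma2_T + s2h),
                  0.05 * diag(C)[iQ], Inf)
      s2R <- clip(diag(C)[iR] - bR^2 * (sigma2_T + s2h),
                  0.05 * diag(C)[iR], Inf)
      rQQ <- clip((C[iQ, iQ] - beta_Q^2 * sigma2_T) / tcrossprod(sqrt(s2Q)),
                  -0.9, 0.9)
      rRR <- clip((C[iR, iR] - bR^2 * sigma2_T) / tcrossprod(sqrt(s2R)),
                  -0.9, 0.9)
      qr_same <- clip((diag(C[iQ, iR, drop = FALSE]) -
                         beta_Q * bR * (sigma2_T + s2h)) /
                        (sqrt(s2Q) * sqrt(s2R)), -0.9, 0.9)
      qr_diff <- clip((C[iQ, iR] - beta_Q * bR * sigma2_T) /
                        tcrossprod(sqrt(s2Q), sqrt(s2R)), -0.9, 0.9)
      me_params(J, beta_Q = beta_Q, beta_M = beta_M, sigma2_T = sigma2_T,
                sigma2_h = s2h, sigma2_Q = s2Q, sigma2_R = s2R, sigma2_M = s2M,
                rho_QQ = rQQ, rho_RR = rRR,
                rho_QR_same = qr_same, rho_QR_diff = qr_diff,
                alpha_Q = mns[iQ], alpha_R = mns[iR], alpha_M = mns[iM])
    } else {
      a <- C[iQ, iR] / bR   # beta_Q * sigma2_T (assuming small same-time corr)
      b <- C[iR, iM] / bR   # beta_M * sigma2_T
      cc <- C[iQ, iM]       # beta_Q * beta_M * sigma2_T
      sigma2_T <- a * b / cc
      if (!is.finite(sigma2_T) || sigma2_T <= 0) stop("moment inversion failed")
      beta_Q <- a / sigma2_T; beta_M <- b / sigma2_T
      me_params(J, beta_Q = beta_Q, beta_M = beta_M, sigma2_T = sigma2_T,
                sigma2_h = 0,
                sigma2_Q = clip(C[iQ, iQ] - beta_Q^2 * sigma2_T,
                                0.05 * C[iQ, iQ], Inf),
                sigma2_R = clip(C[iR, iR] - bR^2 * sigma2_T,
                                0.05 * C[iR, iR], Inf),
                sigma2_M = clip(C[iM, iM] - beta_M^2 * sigma2_T,
                                0.05 * C[iM, iM], Inf),
                alpha_Q = mns[iQ], alpha_R = mns[iR], alpha_M = mns[iM])
    }
  }, error = function(e) neutral())

  ## shrink correlations until the error-correlation matrix is PD
  for (it in 1:20) {
    ok <- tryCatch({ validate_me_params(p, sens); TRUE },
                   error = function(e) FALSE)
    if (ok) break
    p$rho_QQ <- shrink_corr(p$rho_QQ)
    p$rho_RR <- shrink_corr(p$rho_RR)
    p$rho_QR <- p$rho_QR * 0.8
  }
  p
}

shrink_corr <- function(m) {
  d <- diag(m)
  m <- m * 0.8
  diag(m) <- d
  m
}

## ---- maximum likelihood fit ---------------------------------------------

#' Fit the measurement error model by full-cohort maximum likelihood
#'
#' Maximizes the observed-data multivariate-normal likelihood over the
#' free parameters, with the record scaling `beta_R` and the biomarker
#' error correlation `rho_MM` held fixed at the sensitivity setting.
#' Optimization runs unconstrained on transformed parameters (log
#' variances, Fisher-z correlations), starting from moment-based values,
#' via BFGS followed by a PORT (`nlminb`) polish; optional jittered
#' multistarts guard against local optima.
#'
#' @param data an [me_data()] object on the analysis scale.  If it was
#'   produced by [residualize()], intercepts are fixed at zero; otherwise
#'   free time-specific intercepts are estimated.
#' @param sens a [sensitivity_setting()].
#' @param constraints named list of parameter families to fix, e.g.
#'   `list(beta_M = 1, rho_QR_same = 0)` for the recovery-biomarker
#'   configuration, or `list(rho_QQ = 0)` etc.  Values are recycled over
#'   the family.
#' @param intercepts `"auto"` (default: zero when residualized),
#'   `"zero"`, or `"free"`.
#' @param start optional [me_params()] starting values (replaces the
#'   moment-based start).
#' @param multistart number of starts (first from moments, the rest
#'   jittered); the best optimum is kept.
#' @param compute_vcov compute the observed-information variance matrix
#'   of the transformed free parameters (needed for standard errors).
#' @param control passed to [stats::optim()] (BFGS stage).
#' @return An object of class `"me_fit"`: `params` (estimates), `sens`,
#'   `loglik`, `converged`, `vcov` (transformed scale), `map`, `theta`,
#'   `n_individuals`, `patterns` summary, and optimizer `diagnostics`.
#' @examples
#' \donttest{
#' spec <- simulation_spec(n = 2000, seed = 7)
#' d <- residualize(gen_dataset(spec))
#' fit <- fit_ml(d, sensitivity_setting())
#' summary(fit)
#' }
#' @export
fit_ml <- function(data, sens = sensitivity_setting(), constraints = list(),
                   intercepts = c("auto", "zero", "free"), start = NULL,
                   multistart = 1L, compute_vcov = TRUE, control = list()) {
  stopifnot(inherits(data, "me_data"), inherits(sens, "sensitivity_setting"))
  intercepts <- match.arg(intercepts)
  if (intercepts == "auto")
    intercepts <- if (isTRUE(attr(data, "residualized"))) "zero" else "free"
  J <- data$J
  obs <- obs_matrix(data)
  design <- list(Q = which(colSums(!is.na(data$Q)) > 0L),
                 R = which(colSums(!is.na(data$R)) > 0L),
                 M = which(colSums(!is.na(data$M)) > 0L))
  dof <- dof_check(J, design, constraints)
  if (!dof$identified)
    stop(paste0("design not identified; ",
                sprintf("%d free covariance parameters vs %d observed moments. ",
                        dof$n_free, dof$n_moments),
                "Fix additional parameter families via 'constraints'."),
         call. = FALSE)

  map <- param_map(J, constraints, intercepts, design)
  pstats <- make_pattern_stats(data)
  p0 <- if (is.null(start)) moment_start(data, sens, constraints) else start
  template <- unpack_theta(pack_params(p0, map), map, p0)

  negll <- function(theta) {
    p <- unpack_theta(theta, map, template)
    ll <- loglik_stats(p, sens, pstats)
    if (!is.finite(ll)) 1e12 else -ll
  }

  theta0 <- pack_params(p0, map)
  if (!is.finite(negll(theta0)) || negll(theta0) >= 1e12) {
    p0 <- moment_start(subset_me_data(data, seq_len(data$n)), sens)
    p0$rho_QQ <- diag(1, J); p0$rho_RR <- diag(1, J); p0$rho_QR[] <- 0
    theta0 <- pack_params(p0, map)
  }

  run_one <- function(th0) {
    ctl <- utils::modifyList(
      list(maxit = 1000L, reltol = 1e-12,
           parscale = pmax(abs(th0), 0.1)), control)
    o1 <- stats::optim(th0, negll, method = "BFGS", control = ctl)
    best <- list(par = o1$par, value = o1$value,
                 converged = o1$convergence == 0L, msg = "BFGS")
    ## alternate PORT/BFGS polish rounds until the objective stalls: the
    ## likelihood is flat in ratio directions and a single pass can stop
    ## noticeably short of the optimum
    for (round in 1:4) {
      o2 <- stats::nlminb(best$par, negll,
                          scale = 1 / pmax(abs(best$par), 0.1),
                          control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                         iter.max = 500L, eval.max = 2000L))
      improved <- is.finite(o2$objective) && o2$objective <= best$value
      if (improved)
        best <- list(par = o2$par, value = o2$objective,
                     converged = TRUE, msg = o2$message)
      o3 <- stats::optim(best$par, negll, method = "BFGS",
                         control = utils::modifyList(ctl, list(
                           parscale = pmax(abs(best$par), 0.1))))
      gain <- best$value - o3$value
      if (is.finite(o3$value) && o3$value <= best$value)
        best <- list(par = o3$par, value = o3$value, converged = TRUE,
                     msg = "BFGS polish")
      if (!is.na(gain) && gain < 1e-10 * max(1, abs(best$value))) break
    }
    best
  }

  best <- run_one(theta0)
  if (multistart > 1L) {
    for (s in seq_len(multistart - 1L)) {
      th_j <- theta0 + with_seed(1000L + s, stats::rnorm(length(theta0), 0, 0.3))
      cand <- tryCatch(run_one(th_j), error = function(e) NULL)
      if (!is.null(cand) && cand$value < best$value) best <- cand
    }
  }

  theta_hat <- best$par
  params_hat <- unpack_theta(theta_hat, map, template)
  vc <- NULL
  if (compute_vcov) {
    H <- tryCatch(stats::optimHess(theta_hat, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc)) {
        vc <- (vc + t(vc)) / 2
        dimnames(vc) <- list(names(theta_hat), names(theta_hat))
        if (any(diag(vc) < 0)) {
          warning("observed information not positive definite; standard errors unreliable (consider method = \"bootstrap\")")
        }
      }
    }
    if (is.null(vc))
      warning("could not invert the observed information; vcov unavailable")
  }

  pat_sum <- data.frame(
    pattern = vapply(pstats, function(p)
      paste(slot_labels(J)[p$mask], collapse = "+"), character(1)),
    n = vapply(pstats, `[[`, numeric(1), "n"))

  structure(list(params = params_hat, sens = sens, loglik = -best$value,
                 converged = isTRUE(best$converged) && best$value < 1e11,
                 theta = theta_hat, map = map, template = template,
                 vcov = vc, n_individuals = data$n, patterns = pat_sum,
                 constraints = constraints, intercepts = intercepts,
                 diagnostics = list(message = best$msg, neg_loglik = best$value),
                 dof = dof),
            class = "me_fit")
}

#' @export
print.me_fit <- function(x, ...) {
  cat(sprintf("Measurement error model fit (full-cohort ML), n = %d, loglik = %.3f, %s\n",
              x$n_individuals, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  print(x$sens)
  print(x$params)
  invisible(x)
}

#' Natural-scale parameter estimates with delta-method standard errors
#'
#' Maps the fitted transformed parameters and their observed-information
#' variances back to the natural scale (variances, correlations,
#' scalings, intercepts).
#'
#' @param fit an `"me_fit"` result.
#' @return Data frame with `parameter`, `estimate`, `se` for every free
#'   parameter.
#' @export
natural_se <- function(fit) {
  free <- fit$map[fit$map$free, , drop = FALSE]
  est <- vapply(seq_len(nrow(free)), function(r)
    param_get(fit$params, free[r, ]), numeric(1))
  if (is.null(fit$vcov)) se <- rep(NA_real_, nrow(free))
  else {
    sd_th <- sqrt(pmax(diag(fit$vcov), 0))
    deriv <- vapply(seq_len(nrow(free)), function(r) {
      switch(free$transform[r], id = 1, log = est[r],
             atanh = 1 - est[r]^2)
    }, numeric(1))
    se <- abs(deriv) * sd_th
  }
  data.frame(parameter = free$name, estimate = est, se = se,
             stringsAsFactors = FALSE)
}

#' @export
summary.me_fit <- function(object, ...) {
  tab <- natural_se(object)
  fixed <- object$map[!object$map$free & !grepl("^alpha", object$map$name), ]
  out <- list(coefficients = tab,
              fixed = stats::setNames(fixed$fixed_value, fixed$name),
              sens = object$sens, loglik = object$loglik,
              converged = object$converged, n = object$n_individuals,
              patterns = object$patterns)
  class(out) <- "summary.me_fit"
  out
}

#' @export
print.summary.me_fit <- function(x, ...) {
  cat(sprintf("Full-cohort ML fit: n = %d, loglik = %.3f, %s\n", x$n,
              x$loglik, if (x$converged) "converged" else "NOT converged"))
  print(x$sens)
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 5)
  tab$se <- signif(tab$se, 3)
  print(tab, row.names = FALSE)
  if (length(x$fixed)) {
    cat("fixed:", paste(sprintf("%s=%g", names(x$fixed), x$fixed),
                        collapse = ", "), "\n")
  }
  cat(sprintf("missingness patterns: %d\n", nrow(x$patterns)))
  invisible(x)
}
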