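## master seed -> independent substream seeds (covariates, truth, errors,
## missingness, artifacts), all kept below 2^31
substream <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic validation study
#'
#' Bundles everything needed to draw a synthetic dataset with the exact
#' stochastic structure of the measurement error model: latent long-term
#' intake, within-person deviations, the full `3J`-dimensional correlated
#' error draw (including the fixed `rho_MM` and zero self-report--biomarker
#' correlations), covariates with their effect vectors, missingness and
#' raw-scale artifacts.
#'
#' @param n number of individuals.
#' @param params an [me_params()] object; its `gamma_*` vectors must match
#'   the covariate spec column counts.
#' @param sens a [sensitivity_setting()]; supplies `beta_R` and `rho_MM`
#'   used in generation.
#' @param covariates `NULL` or named list with entries `Z_T`, `Z_Q`,
#'   `Z_M`, each a list of column specs:
#'   `list(type = "binary", p = 0.5)`,
#'   `list(type = "continuous", mean = 0, sd = 1)` or
#'   `list(type = "categorical", probs = c(...))` (emitted as
#'   reference-coded dummy columns).  Add `time_varying = TRUE` to redraw
#'   a column at every time point.
#' @param missingness `NULL` or a list: `mechanism` (`"mcar"` or
#'   `"mar"`); for MCAR `rates` (named by slot label, e.g.
#'   `c(R2 = 0.3)`); for MAR `slots` (labels to delete), `driver` (slot
#'   label kept observed), `intercept` and `slope` of the logistic
#'   deletion model on the standardized driver.
#' @param artifacts `NULL` or a list with `zero_rate` (fraction of raw
#'   Q/R values replaced by 0), `outlier_rate` and `outlier_factor`
#'   (fraction of biomarker values multiplied by the factor).  Requires
#'   `raw = TRUE`.
#' @param raw if `TRUE`, Q and R are exponentiated to the original intake
#'   scale (the model generates them on the log scale).
#' @param seed master seed; expanded into independent substreams so that
#'   e.g. changing the missingness mechanism leaves the latent truth
#'   unchanged.
#' @return An object of class `"simulation_spec"`.
#' @seealso [gen_dataset()]
#' @export
simulation_spec <- function(n, params = fv_example_params(),
                            sens = sensitivity_setting(),
                            covariates = NULL, missingness = NULL,
                            artifacts = NULL, raw = FALSE, seed = 1L) {
  stopifnot(n >= 1, inherits(params, "me_params"),
            inherits(sens, "sensitivity_setting"))
  validate_me_params(params, sens)
  if (!is.null(artifacts) && !raw)
    stop("artifact injection operates on the raw scale; set raw = TRUE",
         call. = FALSE)
  if (!is.null(missingness)) {
    mech <- match.arg(missingness$mechanism, c("mcar", "mar"))
    if (mech == "mcar" && any(missingness$rates < 0 | missingness$rates > 1))
      stop("MCAR rates must lie in [0, 1]", call. = FALSE)
    if (mech == "mar" && missingness$driver %in% missingness$slots)
      stop("the MAR driver slot must remain observed", call. = FALSE)
  }
  structure(list(n = as.integer(n), params = params, sens = sens,
                 covariates = covariates, missingness = missingness,
                 artifacts = artifacts, raw = raw, seed = as.integer(seed)),
            class = "simulation_spec")
}

draw_column <- function(spec, n) {
  type <- match.arg(spec$type, c("binary", "continuous", "categorical"))
  switch(type,
    binary = matrix(stats::rbinom(n, 1L, spec$p %||% 0.5), ncol = 1L),
    continuous = matrix(stats::rnorm(n, spec$mean %||% 0, spec$sd %||% 1),
                        ncol = 1L),
    categorical = {
      probs <- spec$probs %||% rep(1 / 3, 3)
      k <- length(probs)
      lev <- sample.int(k, n, replace = TRUE, prob = probs)
      m <- matrix(0, n, k - 1L)
      for (l in 2:k) m[, l - 1L] <- as.numeric(lev == l)
      m
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate covariate design blocks
#'
#' Draws the covariate blocks of a [simulation_spec()] (binary,
#' continuous and reference-coded categorical columns; time-constant
#' unless flagged `time_varying`), reproducibly from the covariate
#' substream of the master seed.
#'
#' @param spec a [simulation_spec()] (or just its `covariates` list, with
#'   `n` and `seed` supplied).
#' @param n,seed used when `spec` is a bare covariate list.
#' @return Named list of blocks `Z_T`, `Z_Q`, `Z_M`, each a list of `J`
#'   design matrices.
#' @export
gen_covariates <- function(spec, n = NULL, seed = NULL) {
  if (inherits(spec, "simulation_spec")) {
    cov_spec <- spec$covariates; n <- spec$n
    seed <- substream(spec$seed, 1L); J <- spec$params$J
  } else {
    cov_spec <- spec; J <- attr(spec, "J") %||% 1L
  }
  if (inherits(spec, "simulation_spec")) J <- spec$params$J
  blocks <- with_seed(seed, {
    lapply(c(Z_T = "Z_T", Z_Q = "Z_Q", Z_M = "Z_M"), function(bn) {
      cols <- cov_spec[[bn]]
      if (is.null(cols) || !length(cols))
        return(rep(list(matrix(numeric(0), n, 0)), J))
      per_time <- lapply(seq_len(J), function(j) NULL)
      drawn <- lapply(cols, function(cs) {
        if (isTRUE(cs$time_varying))
          lapply(seq_len(J), function(j) draw_column(cs, n))
        else rep(list(draw_column(cs, n)), J)
      })
      lapply(seq_len(J), function(j) {
        m <- do.call(cbind, lapply(drawn, `[[`, j))
        colnames(m) <- paste0(sub("Z_", "z", bn), seq_len(ncol(m)))
        m
      })
    })
  })
  blocks
}

#' Generate a synthetic validation dataset
#'
#' Draws, per individual: long-term intake
#' `T_i = gamma_T' Zbar_i + N(0, sigma2_T)`, within-person deviations
#' `h_ij ~ N(0, sigma2_h[j])` (independent over time), and a
#' `3J`-dimensional normal error vector with the model's full error
#' covariance (self-report correlations, `rho_MM` between repeated
#' biomarker errors, zeros between self-reports and biomarker); then
#' assembles the measurements with their intercepts, scalings and
#' covariate effects.  The latent truth is returned as an attribute and
#' never leaks into the measurement columns.  Missingness and raw-scale
#' artifacts from the spec are applied afterwards, from independent
#' substreams.
#'
#' @param spec a [simulation_spec()].
#' @return An [me_data()] object with attributes `truth` (list with `T`,
#'   `T_time`) and `scale`.
#' @export
gen_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  p <- spec$params; sens <- spec$sens
  n <- spec$n; J <- p$J
  blocks <- gen_covariates(spec)
  chk_gamma <- function(g, Z, nm) {
    if (length(g) != ncol(Z[[1]]))
      stop(sprintf("length(%s) = %d does not match %d covariate column(s)",
                   nm, length(g), ncol(Z[[1]])), call. = FALSE)
  }
  chk_gamma(p$gamma_T, blocks$Z_T, "gamma_T")
  chk_gamma(p$gamma_Q, blocks$Z_Q, "gamma_Q")
  chk_gamma(p$gamma_M, blocks$Z_M, "gamma_M")

  ## latent truth: long-term intake and time-specific deviations
  truth <- with_seed(substream(spec$seed, 2L), {
    Zbar <- Reduce(`+`, blocks$Z_T) / J
    mu_T <- if (ncol(Zbar)) drop(Zbar %*% p$gamma_T) else rep(0, n)
    T_i <- mu_T + stats::rnorm(n, 0, sqrt(p$sigma2_T))
    h <- vapply(seq_len(J), function(j) stats::rnorm(n, 0, sqrt(p$sigma2_h[j])),
                numeric(n))
    list(T = T_i, T_time = T_i + h)
  })

  eps <- with_seed(substream(spec$seed, 3L), {
    L <- chol(error_covariance(p, sens))
    matrix(stats::rnorm(n * 3L * J), n, 3L * J) %*% L
  })

  Tt <- truth$T_time
  Q <- R <- M <- matrix(NA_real_, n, J)
  for (j in seq_len(J)) {
    zq <- if (ncol(blocks$Z_Q[[j]])) drop(blocks$Z_Q[[j]] %*% p$gamma_Q) else 0
    zm <- if (ncol(blocks$Z_M[[j]])) drop(blocks$Z_M[[j]] %*% p$gamma_M) else 0
    Q[, j] <- p$alpha_Q[j] + p$beta_Q * Tt[, j] + zq + eps[, j]
    R[, j] <- p$alpha_R[j] + sens$beta_R * Tt[, j] + eps[, J + j]
    M[, j] <- p$alpha_M[j] + p$beta_M * Tt[, j] + zm + eps[, 2L * J + j]
  }
  d <- me_data(Q, R, M, Z_T = blocks$Z_T, Z_Q = blocks$Z_Q, Z_M = blocks$Z_M,
               scale = "analysis")
  attr(d, "truth") <- truth

  if (spec$raw) {
    d$Q <- exp(d$Q); d$R <- exp(d$R)
    attr(d, "scale") <- "raw"
  }
  if (!is.null(spec$artifacts))
    d <- inject_artifacts(d, spec$artifacts, seed = substream(spec$seed, 5L))
  if (!is.null(spec$missingness))
    d <- apply_missingness(d, spec$missingness, seed = substream(spec$seed, 4L))
  d
}

#' Apply MCAR or MAR missingness to a dataset
#'
#' MCAR deletes each stated slot independently at its rate.  MAR deletes
#' the stated slots with probability `plogis(intercept + slope * z)`,
#' where `z` is the standardized value of the driver slot (which must
#' remain observed), so that missingness depends only on an observed
#' quantity and full-cohort likelihood fitting remains valid.
#' Individuals losing every measurement are dropped (with a message).
#'
#' @param data an [me_data()] object.
#' @param missingness see [simulation_spec()].
#' @param seed integer seed (substream of the master seed when called
#'   from [gen_dataset()]).
#' @return The dataset with `NA`s inserted.
#' @export
apply_missingness <- function(data, missingness, seed = 1L) {
  mech <- match.arg(missingness$mechanism, c("mcar", "mar"))
  obs <- obs_matrix(data)
  labs <- colnames(obs)
  del <- with_seed(seed, {
    if (mech == "mcar") {
      rates <- missingness$rates
      if (is.null(names(rates))) {
        if (length(rates) == 1L) rates <- stats::setNames(rep(rates, length(labs)), labs)
        else if (length(rates) == length(labs)) names(rates) <- labs
        else stop("MCAR 'rates' must be named by slot, scalar, or length 3J",
                  call. = FALSE)
      }
      d <- matrix(FALSE, data$n, length(labs), dimnames = list(NULL, labs))
      for (s in names(rates))
        d[, s] <- stats::runif(data$n) < rates[[s]]
      d
    } else {
      drv <- obs[, missingness$driver]
      if (anyNA(drv)) stop("MAR driver slot has missing values", call. = FALSE)
      z <- (drv - mean(drv)) / stats::sd(drv)
      pr <- stats::plogis(missingness$intercept + missingness$slope * z)
      d <- matrix(FALSE, data$n, length(labs), dimnames = list(NULL, labs))
      for (s in missingness$slots)
        d[, s] <- stats::runif(data$n) < pr
      d
    }
  })
  put <- function(m, cols, dl) {
    m[dl[, cols, drop = FALSE]] <- NA_real_
    m
  }
  J <- data$J
  data$Q <- put(data$Q, seq_len(J), del)
  data$R <- put(data$R, J + seq_len(J), del)
  data$M <- put(data$M, 2L * J + seq_len(J), del)
  empty <- rowSums(!is.na(obs_matrix(data))) == 0L
  if (any(empty)) {
    message(sprintf("apply_missingness: dropping %d individual(s) with no remaining observation",
                    sum(empty)))
    data <- subset_me_data(data, !empty)
  }
  data
}

#' Inject raw-scale data artifacts
#'
#' Emulates two artifacts of real dietary validation data on the original
#' measurement scale: reported zero intakes in the self-report
#' instruments (a stated fraction of Q/R values replaced by 0) and
#' spuriously high biomarker values (e.g. from supplement use; a stated
#' fraction multiplied by `outlier_factor`).  [preprocess()] is expected
#' to flag both as missing.
#'
#' @param data an [me_data()] object on the raw scale.
#' @param artifacts list with `zero_rate`, `outlier_rate`,
#'   `outlier_factor` (defaults 0, 0, 5).
#' @param seed integer seed.
#' @return The modified dataset, with attribute `"artifact_idx"` listing
#'   the affected cells.
#' @export
inject_artifacts <- function(data, artifacts, seed = 1L) {
  if (!identical(attr(data, "scale"), "raw"))
    stop("inject_artifacts requires raw-scale data", call. = FALSE)
  zr <- artifacts$zero_rate %||% 0
  or <- artifacts$outlier_rate %||% 0
  of <- artifacts$outlier_factor %||% 5
  idx <- with_seed(seed, {
    zq <- which(!is.na(data$Q) & stats::runif(length(data$Q)) < zr)
    zrw <- which(!is.na(data$R) & stats::runif(length(data$R)) < zr)
    om <- which(!is.na(data$M) & stats::runif(length(data$M)) < or)
    list(zero_Q = zq, zero_R = zrw, outlier_M = om)
  })
  data$Q[idx$zero_Q] <- 0
  data$R[idx$zero_R] <- 0
  data$M[idx$outlier_M] <- data$M[idx$outlier_M] * of
  attr(data, "artifact_idx") <- idx
  data
}
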