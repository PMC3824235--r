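#' Grid of sensitivity values for the unidentified parameters
#'
#' Default grid: record scaling `beta_R` in \{1, 0.75, 0.5\} (spanning the
#' range reported by recovery-biomarker studies of self-reported intake)
#' crossed with biomarker error correlation `rho_MM` in \{0, 0.2, 0.4\}.
#'
#' @param beta_R_values positive values, no duplicates.
#' @param rho_MM_values values in `[0, 1)`, no duplicates.
#' @return An object of class `"sensitivity_grid"`.
#' @export
sensitivity_grid <- function(beta_R_values = c(1, 0.75, 0.5),
                             rho_MM_values = c(0, 0.2, 0.4)) {
  if (!length(beta_R_values) || !length(rho_MM_values))
    stop("grid value lists must be nonempty", call. = FALSE)
  if (anyDuplicated(beta_R_values) || anyDuplicated(rho_MM_values))
    stop("grid values must not contain duplicates", call. = FALSE)
  if (any(beta_R_values <= 0)) stop("beta_R values must be positive", call. = FALSE)
  if (any(rho_MM_values < 0 | rho_MM_values >= 1))
    stop("rho_MM values must lie in [0, 1)", call. = FALSE)
  structure(list(beta_R_values = as.numeric(beta_R_values),
                 rho_MM_values = as.numeric(rho_MM_values)),
            class = "sensitivity_grid")
}

## the exact likelihood-preserving reparameterization when the fixed
## record scaling moves from beta_R to c * beta_R
rescale_params <- function(params, c_) {
  params$beta_Q <- params$beta_Q * c_
  params$beta_M <- params$beta_M * c_
  params$sigma2_T <- params$sigma2_T / c_^2
  params$sigma2_h <- params$sigma2_h / c_^2
  params
}

data_fingerprint <- function(data) {
  obs <- obs_matrix(data)
  c(n = data$n, J = data$J,
    sum = sum(obs, na.rm = TRUE), n_obs = sum(!is.na(obs)))
}

#' Run the sensitivity analysis over a grid of fixed (beta_R, rho_MM)
#'
#' Fits the model once per grid cell on the identical dataset.  Cells are
#' independent fits from their own moment-based starting values, so
#' results do not depend on grid ordering or scheduling; a cell that
#' fails to converge is recorded with its diagnostic rather than dropped.
#' When the dataset carries covariates and is not residualized, it is
#' residualized once up front (shared by all cells) and covariate effects
#' are estimated per cell from the raw data.
#'
#' @param data an [me_data()] object on the analysis scale.
#' @param grid a [sensitivity_grid()].
#' @param constraints,multistart,control passed to [fit_ml()].
#' @param gammas also estimate covariate effects per cell (requires
#'   covariates and non-residualized input).
#' @param warm_start start each cell after the first of its `rho_MM` row
#'   from the exactly rescaled solution of that row's first `beta_R`
#'   cell (the likelihood is invariant under this rescaling, so this
#'   only sharpens convergence; results remain start-independent to
#'   optimizer tolerance).
#' @return An object of class `"sensitivity_result"`: data frame `cells`
#'   (`beta_R`, `rho_MM`, `converged`, `loglik`), lists `fits` and
#'   `derived` (per cell; derived tables carry delta SEs), optional
#'   `gamma` list, and the shared `fingerprint`.
#' @export
run_grid <- function(data, grid = sensitivity_grid(), constraints = list(),
                     multistart = 1L, control = list(), gammas = NULL,
                     warm_start = TRUE) {
  stopifnot(inherits(data, "me_data"), inherits(grid, "sensitivity_grid"))
  has_cov <- ncol(data$Z_T[[1]]) + ncol(data$Z_Q[[1]]) + ncol(data$Z_M[[1]]) > 0L
  raw <- data
  if (has_cov && !isTRUE(attr(data, "residualized")))
    data <- residualize(data)
  if (is.null(gammas)) gammas <- has_cov && !isTRUE(attr(raw, "residualized"))

  cells <- expand.grid(beta_R = grid$beta_R_values,
                       rho_MM = grid$rho_MM_values,
                       KEEP.OUT.ATTRS = FALSE)
  fits <- vector("list", nrow(cells))
  ders <- vector("list", nrow(cells))
  gams <- if (gammas) vector("list", nrow(cells)) else NULL
  cells$converged <- NA
  cells$loglik <- NA_real_
  cells$message <- ""
  for (i in seq_len(nrow(cells))) {
    sens <- sensitivity_setting(cells$beta_R[i], cells$rho_MM[i])
    start <- NULL
    if (warm_start) {
      anchor <- which(cells$rho_MM == cells$rho_MM[i] &
                        cells$beta_R == grid$beta_R_values[1])
      if (anchor != i && !is.null(fits[[anchor]]) &&
          isTRUE(fits[[anchor]]$converged))
        start <- rescale_params(fits[[anchor]]$params,
                                cells$beta_R[i] / cells$beta_R[anchor])
    }
    res <- tryCatch(
      fit_ml(data, sens, constraints = constraints, multistart = multistart,
             control = control, start = start),
      error = function(e) e)
    if (inherits(res, "error")) {
      cells$converged[i] <- FALSE
      cells$message[i] <- conditionMessage(res)
      next
    }
    fits[[i]] <- res
    cells$converged[i] <- res$converged
    cells$loglik[i] <- res$loglik
    if (!res$converged) cells$message[i] <- "optimizer did not converge"
    ders[[i]] <- tryCatch(derived_quantities(res), error = function(e) NULL)
    if (gammas && res$converged) {
      gams[[i]] <- list(
        gamma_T = if (ncol(raw$Z_T[[1]])) tryCatch(
          estimate_gamma_T(raw, sens), error = function(e) NULL),
        gamma_Q = if (ncol(raw$Z_Q[[1]])) tryCatch(
          estimate_gamma_secondary(raw, res, "Q"), error = function(e) NULL),
        gamma_M = if (ncol(raw$Z_M[[1]])) tryCatch(
          estimate_gamma_secondary(raw, res, "M"), error = function(e) NULL))
    }
  }
  structure(list(cells = cells, fits = fits, derived = ders, gamma = gams,
                 grid = grid, fingerprint = data_fingerprint(data)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %d cells (%d converged), n = %d\n",
              nrow(x$cells), sum(x$cells$converged, na.rm = TRUE),
              x$fingerprint[["n"]]))
  print(x$cells[, c("beta_R", "rho_MM", "converged", "loglik")],
        row.names = FALSE)
  invisible(x)
}

fmt_est <- function(est, se) {
  ifelse(is.na(est), "NC",
         sprintf("%.3g (%.2g)", est, ifelse(is.na(se), NA, se)))
}

#' Summary tables of a sensitivity analysis
#'
#' Assembles the grid results into a table with `rho_MM` values as
#' columns: `layout = "rdr"` rows are (quantity, instrument, time,
#' exposure, `beta_R`) for RDRs and correlations; `layout = "params"`
#' rows are (parameter, `beta_R`); `layout = "covariates"` rows are
#' (block, term, `beta_R`).  Cells show `estimate (se)`; non-converged
#' cells show `"NC"`.  A machine-readable twin in long format is attached
#' as attribute `"long"` and written to `csv` when requested.
#'
#' @param result a [run_grid()] result.
#' @param layout `"rdr"`, `"params"` or `"covariates"`.
#' @param csv optional path: the long-format table is written as CSV.
#' @return A data frame (formatted strings), with attribute `"long"`.
#' @export
summarize_grid <- function(result, layout = c("rdr", "params", "covariates"),
                           csv = NULL) {
  layout <- match.arg(layout)
  stopifnot(inherits(result, "sensitivity_result"))
  cells <- result$cells
  if (!any(cells$converged, na.rm = TRUE))
    stop("no successfully fitted cells to summarize", call. = FALSE)

  long <- list()
  for (i in seq_len(nrow(cells))) {
    if (layout == "rdr") {
      d <- result$derived[[i]]
      if (is.null(d)) next
      d <- cbind(beta_R = cells$beta_R[i], rho_MM = cells$rho_MM[i], d)
      long[[length(long) + 1L]] <- d
    } else if (layout == "params") {
      f <- result$fits[[i]]
      if (is.null(f)) next
      tab <- natural_se(f)
      long[[length(long) + 1L]] <- data.frame(
        beta_R = cells$beta_R[i], rho_MM = cells$rho_MM[i],
        parameter = tab$parameter, estimate = tab$estimate, se = tab$se)
    } else {
      g <- result$gamma[[i]]
      if (is.null(g)) next
      for (bn in names(g)) {
        if (is.null(g[[bn]])) next
        long[[length(long) + 1L]] <- data.frame(
          beta_R = cells$beta_R[i], rho_MM = cells$rho_MM[i],
          block = bn, term = g[[bn]]$term,
          estimate = g[[bn]]$estimate, se = g[[bn]]$se)
      }
    }
  }
  if (!length(long))
    stop(sprintf("no results available for layout \"%s\"", layout), call. = FALSE)
  long <- do.call(rbind, long)
  rownames(long) <- NULL

  idcols <- setdiff(names(long), c("rho_MM", "estimate", "se"))
  key <- do.call(paste, c(long[idcols], sep = " | "))
  ukey <- unique(key)
  rhos <- sort(unique(long$rho_MM))
  wide <- long[match(ukey, key), idcols, drop = FALSE]
  for (rh in rhos) {
    col <- rep("NC", length(ukey))
    sel <- long$rho_MM == rh
    m <- match(key[sel], ukey)
    col[m] <- fmt_est(long$estimate[sel], long$se[sel])
    wide[[sprintf("rho_MM=%g", rh)]] <- col
  }
  rownames(wide) <- NULL
  attr(wide, "long") <- long
  if (!is.null(csv)) utils::write.csv(long, csv, row.names = FALSE)
  wide
}
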