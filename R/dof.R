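#' Identifiability (degrees-of-freedom) check for a study design
#'
#' Counts the free covariance-structure parameters of the model implied by
#' a design (which measurement slots exist) and a set of constraints, and
#' compares with the number of distinct observed second moments.  This is
#' a necessary counting condition only: `free <= moments` does not by
#' itself guarantee identification (rank conditions can still fail for
#' special configurations), which the report notes.
#'
#' Counting rules: `sigma2_T` is always free; the within-person variances
#' `sigma2_h[j]` are free only when `J >= 2` (for a single time point they
#' are not separable from `sigma2_T` and are fixed at 0); one error
#' variance per existing slot; `beta_Q` / `beta_M` free when the
#' instrument has any slot (`beta_R` is always fixed by the sensitivity
#' setting, as is `rho_MM`); one correlation per existing within- or
#' cross-instrument pair of self-report slots unless its family is
#' constrained.  Intercepts and means are not counted on either side.
#'
#' @param J number of time points.
#' @param design named list of time-index vectors giving which slots
#'   exist, e.g. `list(Q = 1, R = 1:2, M = 1:2)`.  Default: all
#'   instruments at all `J` time points.
#' @param constraints named list of fixed parameter families as accepted
#'   by [fit_ml()], e.g. `list(rho_QR_same = 0, beta_M = 1)`.
#' @return A list of class `"dof_report"`: `n_free`, `n_moments`,
#'   `identified` (logical: `n_free <= n_moments`), `free` (named counts),
#'   `note`.
#' @examples
#' dof_check(2)                                  # 17 free vs 21 moments
#' dof_check(1)                                  # 7 vs 6: not identified
#' dof_check(1, constraints = list(rho_QR_same = 0))  # 6 vs 6
#' @export
dof_check <- function(J, design = NULL, constraints = list()) {
  J <- as.integer(J)
  if (J < 1L) stop("'J' must be >= 1", call. = FALSE)
  if (is.null(design)) design <- list(Q = seq_len(J), R = seq_len(J), M = seq_len(J))
  design <- lapply(design, function(v) sort(unique(as.integer(v))))
  for (nm in names(design))
    if (length(design[[nm]]) && (min(design[[nm]]) < 1L || max(design[[nm]]) > J))
      stop("design time indices must lie in 1..J", call. = FALSE)
  nQ <- length(design$Q); nR <- length(design$R); nM <- length(design$M)
  p <- nQ + nR + nM
  if (p == 0L) stop("empty design: no measurement slots", call. = FALSE)
  fixed <- names(constraints)
  free <- c(
    sigma2_T = 1L,
    sigma2_h = if (J >= 2L && !"sigma2_h" %in% fixed) J else 0L,
    beta_Q   = if (nQ > 0L && !"beta_Q" %in% fixed) 1L else 0L,
    beta_M   = if (nM > 0L && !"beta_M" %in% fixed) 1L else 0L,
    error_variances = p,
    rho_QQ = if (!"rho_QQ" %in% fixed) choose(nQ, 2L) else 0L,
    rho_RR = if (!"rho_RR" %in% fixed) choose(nR, 2L) else 0L,
    rho_QR_same = if (!"rho_QR_same" %in% fixed)
      length(intersect(design$Q, design$R)) else 0L,
    rho_QR_diff = if (!"rho_QR_diff" %in% fixed)
      sum(outer(design$Q, design$R, "!=")) else 0L
  )
  n_free <- sum(free)
  n_moments <- (p * (p + 1L)) %/% 2L
  structure(list(
    n_free = n_free, n_moments = n_moments,
    identified = n_free <= n_moments, free = free,
    note = paste("counting condition only; a rank condition must also hold",
                 "(e.g. at least two biomarker time points are needed to",
                 "separate biomarker error variance from intake variance)")),
    class = "dof_report")
}

#' @export
print.dof_report <- function(x, ...) {
  cat(sprintf("Identifiability check: %d free covariance parameters vs %d observed second moments -> %s\n",
              x$n_free, x$n_moments,
              if (x$identified) "identified (counting condition met)" else "NOT identified"))
  cat("  free parameters:",
      paste(sprintf("%s=%d", names(x$free)[x$free > 0], x$free[x$free > 0]),
            collapse = ", "), "\n")
  cat("  note:", x$note, "\n")
  invisible(x)
}
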