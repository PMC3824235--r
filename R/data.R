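#' Validation dataset container
#'
#' Wide per-individual measurements for a dietary validation study:
#' questionnaire `Q`, food record `R` and surrogate biomarker `M`, each an
#' `n x J` matrix with `NA` for missing values, plus covariate design
#' blocks `Z_T`, `Z_Q`, `Z_M` (lists of length `J` of `n x p` numeric
#' matrices; categorical covariates pre-encoded as design columns).  The
#' food record carries no own covariate block (`gamma_R == 0`).
#'
#' @param Q,R,M `n x J` numeric matrices (or vectors for `J = 1`).
#' @param Z_T,Z_Q,Z_M covariate blocks: `NULL` (none), a single `n x p`
#'   matrix (time-constant), or a list of `J` matrices (time-varying).
#' @param id individual identifiers (unique).
#' @param scale `"analysis"` (self-reports logged) or `"raw"`.
#' @return An object of class `"me_data"`.
#' @export
me_data <- function(Q, R, M, Z_T = NULL, Z_Q = NULL, Z_M = NULL,
                    id = NULL, scale = c("analysis", "raw")) {
  scale <- match.arg(scale)
  as_mat <- function(x) {
    if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
    storage.mode(x) <- "double"
    x
  }
  Q <- as_mat(Q); R <- as_mat(R); M <- as_mat(M)
  n <- nrow(Q); J <- ncol(Q)
  if (nrow(R) != n || nrow(M) != n || ncol(R) != J || ncol(M) != J)
    stop("Q, R, M must have identical dimensions", call. = FALSE)
  as_block <- function(Z, prefix) {
    if (is.null(Z)) Z <- matrix(numeric(0), n, 0)
    if (!is.list(Z)) Z <- rep(list(Z), J)
    if (length(Z) != J) stop("covariate block must have one matrix per time point",
                             call. = FALSE)
    lapply(Z, function(m) {
      m <- as_mat(m)
      if (nrow(m) != n) stop("covariate block row count differs from n",
                             call. = FALSE)
      if (ncol(m) > 0 && is.null(colnames(m)))
        colnames(m) <- paste0(prefix, seq_len(ncol(m)))
      m
    })
  }
  if (is.null(id)) id <- seq_len(n)
  if (anyDuplicated(id)) stop("'id' must be unique", call. = FALSE)
  d <- structure(list(J = J, n = n, Q = Q, R = R, M = M,
                      Z_T = as_block(Z_T, "zT"), Z_Q = as_block(Z_Q, "zQ"),
                      Z_M = as_block(Z_M, "zM"), id = id),
                 class = "me_data", scale = scale)
  keep <- rowSums(!is.na(obs_matrix(d))) > 0L
  if (!all(keep)) {
    message(sprintf("dropping %d individual(s) with no observed measurement",
                    sum(!keep)))
    d <- subset_me_data(d, keep)
  }
  d
}

#' @export
print.me_data <- function(x, ...) {
  obs <- !is.na(obs_matrix(x))
  cat(sprintf("Dietary validation dataset: n = %d individuals, J = %d time points (%s scale)\n",
              x$n, x$J, attr(x, "scale")))
  cat("  observed per slot:",
      paste(sprintf("%s:%d", colnames(obs), colSums(obs)), collapse = " "), "\n")
  pz <- vapply(list(Z_T = x$Z_T, Z_Q = x$Z_Q, Z_M = x$Z_M),
               function(b) ncol(b[[1]]), integer(1))
  cat("  covariate columns: ", paste(sprintf("%s:%d", names(pz), pz),
                                     collapse = " "), "\n")
  if (isTRUE(attr(x, "residualized"))) cat("  (residualized)\n")
  invisible(x)
}

#' Observed-measurement matrix in slot order
#'
#' @param data an [me_data()] object.
#' @return `n x 3J` matrix with columns `Q1..QJ, R1..RJ, M1..MJ`.
#' @export
obs_matrix <- function(data) {
  m <- cbind(data$Q, data$R, data$M)
  colnames(m) <- slot_labels(data$J)
  m
}

#' Row-subset a validation dataset
#'
#' Used for complete-case comparisons and stratified (subset) sensitivity
#' analyses.
#'
#' @param data an [me_data()] object.
#' @param keep logical or integer row index.
#' @return The subsetted `"me_data"` object (attributes preserved).
#' @export
subset_me_data <- function(data, keep) {
  d <- data
  d$Q <- data$Q[keep, , drop = FALSE]
  d$R <- data$R[keep, , drop = FALSE]
  d$M <- data$M[keep, , drop = FALSE]
  d$Z_T <- lapply(data$Z_T, function(m) m[keep, , drop = FALSE])
  d$Z_Q <- lapply(data$Z_Q, function(m) m[keep, , drop = FALSE])
  d$Z_M <- lapply(data$Z_M, function(m) m[keep, , drop = FALSE])
  d$id <- data$id[keep]
  d$n <- length(d$id)
  tr <- attr(data, "truth")
  if (!is.null(tr))
    attr(d, "truth") <- list(T = tr$T[keep], T_time = tr$T_time[keep, , drop = FALSE])
  d
}

#' Group individuals by missingness pattern
#'
#' Partitions the dataset by the set of observed slots; the groups are the
#' unit of computation of the full-cohort likelihood (one covariance
#' submatrix and one set of sufficient statistics per pattern).
#'
#' @param data an [me_data()] object.
#' @return List of patterns, each a list with `mask` (logical over the
#'   `3J` slots), `idx` (row indices) and `n`.  Counts sum to `data$n`.
#' @export
group_patterns <- function(data) {
  obs <- !is.na(obs_matrix(data))
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(data$n), key)
  out <- lapply(groups, function(idx) {
    list(mask = obs[idx[1L], ], idx = idx, n = length(idx))
  })
  names(out) <- NULL
  out[order(-vapply(out, `[[`, integer(1), "n"))]
}

#' Convert a long table to the wide per-individual layout
#'
#' Convenience converter for datasets stored with one row per individual
#' and time point.
#'
#' @param df data frame in long format.
#' @param id,time names of the identifier and time-point columns.
#' @param values names of the measurement/covariate columns to spread.
#' @return Wide data frame with one row per individual and columns
#'   `<value>_<time>`.
#' @export
long_to_wide <- function(df, id = "id", time = "time", values) {
  stopifnot(all(c(id, time, values) %in% names(df)))
  times <- sort(unique(df[[time]]))
  ids <- unique(df[[id]])
  out <- data.frame(id = ids)
  names(out) <- id
  for (v in values) for (tm in times) {
    col <- df[[v]][match(paste(ids, tm), paste(df[[id]], df[[time]]))]
    out[[paste0(v, "_", tm)]] <- col
  }
  out
}
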