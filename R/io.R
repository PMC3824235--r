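#' Study configuration: column mapping, transforms and filters
#'
#' Describes how a wide CSV maps onto the model's measurement slots and
#' covariate blocks, which instruments are log-transformed, and the
#' preprocessing filters.  Serializes to YAML via [write_config()] /
#' [read_config()] for use from the command line.
#'
#' @param columns named list: `Q`, `R`, `M` are character vectors of
#'   length `J` (CSV column per time point); `Z_T`, `Z_Q`, `Z_M` are
#'   either character vectors (time-constant covariate columns) or lists
#'   of `J` character vectors (time-varying).  Measurement columns must
#'   be disjoint across the three roles.
#' @param transform named list per instrument: `"log"` or `"none"`.
#'   Default: log for the self-reports, none for the biomarker.
#' @param zeros_to_missing treat zero (and negative) values of
#'   log-transformed instruments as missing before logging.
#' @param outlier_rule list with `enabled`, `multiplier` (default 2) and
#'   `quantile` (default 0.75): biomarker values strictly above
#'   `Q(quantile) + multiplier * IQR`, computed per time point over
#'   non-missing values with linear-interpolation quantiles, are set
#'   missing.
#' @param grid a [sensitivity_grid()].
#' @param seed integer seed recorded in the config.
#' @param fit_options list passed on to [fit_ml()] (e.g. `constraints`,
#'   `multistart`).
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(columns,
                         transform = list(Q = "log", R = "log", M = "none"),
                         zeros_to_missing = TRUE,
                         outlier_rule = list(enabled = TRUE, multiplier = 2,
                                             quantile = 0.75),
                         grid = sensitivity_grid(), seed = 1L,
                         fit_options = list()) {
  stopifnot(all(c("Q", "R", "M") %in% names(columns)))
  J <- length(columns$Q)
  if (length(columns$R) != J || length(columns$M) != J)
    stop("Q, R, M column mappings must have equal length J", call. = FALSE)
  meas <- c(columns$Q, columns$R, columns$M)
  if (anyDuplicated(meas))
    stop(sprintf("column mapped to two measurement roles: %s",
                 paste(unique(meas[duplicated(meas)]), collapse = ", ")),
         call. = FALSE)
  or <- utils::modifyList(list(enabled = TRUE, multiplier = 2, quantile = 0.75),
                          as.list(outlier_rule))
  if (or$multiplier <= 0) stop("outlier multiplier must be > 0", call. = FALSE)
  structure(list(columns = columns, J = J, transform = transform,
                 zeros_to_missing = isTRUE(zeros_to_missing),
                 outlier_rule = or, grid = grid, seed = as.integer(seed),
                 fit_options = fit_options),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `"study_config"`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$grid <- unclass(lst$grid)
  writeLines(yaml::as.yaml(lst, precision = 17L), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  study_config(columns = lst$columns, transform = lst$transform,
               zeros_to_missing = lst$zeros_to_missing,
               outlier_rule = lst$outlier_rule,
               grid = sensitivity_grid(lst$grid$beta_R_values,
                                       lst$grid$rho_MM_values),
               seed = lst$seed,
               fit_options = lst$fit_options %||% list())
}

#' Read a wide validation-study CSV
#'
#' One row per individual; empty cells are missing.  Columns are mapped
#' to measurement slots and covariate blocks by the [study_config()].
#'
#' @param path CSV file with a header row.
#' @param config a [study_config()].
#' @return An [me_data()] object on the raw scale.
#' @export
read_dataset <- function(path, config) {
  stopifnot(inherits(config, "study_config"))
  df <- utils::read.csv(path, check.names = FALSE)
  need <- unlist(config$columns, use.names = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("mapped column(s) not in file: %s; available: %s",
                 paste(missing_cols, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  getnum <- function(cols) {
    m <- as.matrix(df[cols])
    if (is.character(m)) {
      m2 <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
      bad <- which(is.na(m2) & !is.na(m) & nzchar(trimws(m)), arr.ind = TRUE)
      if (nrow(bad))
        stop(sprintf("non-numeric cell in column '%s', row %d",
                     cols[bad[1, 2]], bad[1, 1]), call. = FALSE)
      m <- m2
    }
    m
  }
  block <- function(spec) {
    if (is.null(spec) || !length(spec)) return(NULL)
    if (!is.list(spec)) {
      m <- getnum(spec); colnames(m) <- spec
      return(m)
    }
    lapply(spec, function(cols) {
      m <- getnum(cols); colnames(m) <- cols; m
    })
  }
  id <- if ("id" %in% names(df)) df$id else seq_len(nrow(df))
  d <- me_data(getnum(config$columns$Q), getnum(config$columns$R),
               getnum(config$columns$M),
               Z_T = block(config$columns$Z_T),
               Z_Q = block(config$columns$Z_Q),
               Z_M = block(config$columns$Z_M),
               id = id, scale = "raw")
  message(sprintf("read %d rows, %d columns mapped from %s",
                  nrow(df), length(need), path))
  d
}

#' Write a dataset to a wide CSV
#'
#' Inverse of [read_dataset()]: measurement and covariate columns are
#' written under the names of the column mapping (or default labels).
#'
#' @param data an [me_data()] object.
#' @param path output CSV path.
#' @param config optional [study_config()] providing column names.
#' @export
write_dataset <- function(data, path, config = NULL) {
  J <- data$J
  nm <- if (!is.null(config)) config$columns else
    list(Q = paste0("Q", seq_len(J)), R = paste0("R", seq_len(J)),
         M = paste0("M", seq_len(J)))
  df <- data.frame(id = data$id)
  for (X in c("Q", "R", "M")) {
    m <- data[[X]]
    colnames(m) <- nm[[X]]
    df <- cbind(df, m)
  }
  for (bn in c("Z_T", "Z_Q", "Z_M")) {
    b <- data[[bn]]
    if (ncol(b[[1]]) == 0L) next
    tv <- !all(vapply(b, function(m) identical(m, b[[1]]), logical(1)))
    if (tv) {
      for (j in seq_len(J)) {
        m <- b[[j]]
        colnames(m) <- paste0(colnames(m), "_t", j)
        df <- cbind(df, m)
      }
    } else df <- cbind(df, b[[1]])
  }
  ## doubles at 17 significant digits so read_dataset is value-exact
  df[] <- lapply(df, function(v)
    if (is.double(v)) ifelse(is.na(v), NA, sprintf("%.17g", v)) else v)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Preprocess a raw-scale dataset to the analysis scale
#'
#' Applies, in order: (1) zero/negative self-report values set missing
#' for log-transformed instruments (reported zero intakes cannot be
#' logged and are treated as missing); (2) biomarker high-outlier filter
#' -- values strictly above `Q(q) + m * IQR` per time point (defaults
#' `q = 0.75`, `m = 2`; linear-interpolation quantiles, the common
#' statistical-software convention) are set missing, as such values
#' typically reflect supplement use rather than dietary intake; (3) log
#' transform of the configured instruments.  Exclusion counts are logged
#' and stored in attribute `"preprocess_log"`.  Idempotent: data already
#' on the analysis scale are returned unchanged.
#'
#' @param data an [me_data()] object on the raw scale.
#' @param config a [study_config()].
#' @return The dataset on the analysis scale.
#' @export
preprocess <- function(data, config) {
  stopifnot(inherits(data, "me_data"), inherits(config, "study_config"))
  if (identical(attr(data, "scale"), "analysis")) return(data)
  logX <- vapply(c(Q = "Q", R = "R", M = "M"),
                 function(X) identical(config$transform[[X]], "log"),
                 logical(1))
  counts <- list()
  for (X in c("Q", "R", "M")) {
    if (config$zeros_to_missing && logX[[X]]) {
      bad <- !is.na(data[[X]]) & data[[X]] <= 0
      counts[[paste0("zero_", X)]] <- sum(bad)
      data[[X]][bad] <- NA_real_
    }
  }
  if (isTRUE(config$outlier_rule$enabled)) {
    nout <- integer(data$J)
    for (j in seq_len(data$J)) {
      x <- data$M[, j]
      ok <- !is.na(x)
      if (sum(ok) < 4L) next
      q3 <- stats::quantile(x[ok], config$outlier_rule$quantile, type = 7,
                            names = FALSE)
      q1 <- stats::quantile(x[ok], 1 - config$outlier_rule$quantile, type = 7,
                            names = FALSE)
      thr <- q3 + config$outlier_rule$multiplier * (q3 - q1)
      out <- ok & x > thr
      nout[j] <- sum(out)
      data$M[out, j] <- NA_real_
    }
    counts$outlier_M <- nout
  }
  for (X in c("Q", "R", "M")) if (logX[[X]]) data[[X]] <- log(data[[X]])
  ## an instrument with no remaining observations cannot enter the model
  for (X in c("Q", "R", "M"))
    if (all(is.na(data[[X]])))
      stop(sprintf("instrument %s entirely missing after filtering", X),
           call. = FALSE)
  attr(data, "scale") <- "analysis"
  attr(data, "preprocess_log") <- counts
  message(sprintf("preprocess: %s",
                  paste(sprintf("%s=%s", names(counts),
                                vapply(counts, function(v)
                                  paste(v, collapse = "/"), character(1))),
                        collapse = ", ")))
  data
}
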