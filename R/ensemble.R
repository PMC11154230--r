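#' A single kinetic parameter vector
#'
#' @param values Named numeric vector of strictly positive rate constants
#'   (per-second or per-second-per-molecule, as dictated by reaction order).
#' @param log_posterior Optional log-posterior value from Bayesian
#'   calibration.
#' @param weight Optional nonnegative weight.
#' @return A `parameter_vector`.
#' @export
parameter_vector <- function(values, log_posterior = NA_real_,
                             weight = NA_real_) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("parameter values must be named")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all kinetic parameters must be finite and > 0")
  }
  if (!is.na(weight) && (!is.finite(weight) || weight < 0)) {
    stop("weight must be finite and nonnegative")
  }
  structure(list(values = stats::setNames(as.numeric(values), names(values)),
                 log_posterior = as.numeric(log_posterior),
                 weight = as.numeric(weight)),
            class = "parameter_vector")
}

#' A weighted ensemble of parameter vectors
#'
#' The uncertainty object all analyses iterate over: one row per parameter
#' vector, with normalized posterior weights. Weights may be supplied
#' directly, derived from log-posteriors (overflow-safe softmax), or left
#' uniform.
#'
#' @param values Numeric matrix (rows = vectors) with parameter names as
#'   column names, or a data frame.
#' @param log_posterior Optional numeric vector of per-row log-posteriors.
#' @param weights Optional nonnegative per-row weights (normalized
#'   internally).
#' @return A `parameter_ensemble` with elements `values`, `log_posterior`
#'   and `weights` (normalized to sum to 1).
#' @export
parameter_ensemble <- function(values, log_posterior = NULL, weights = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("ensemble columns must be named")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("ensemble contains non-finite or non-positive rate values")
  }
  n <- nrow(values)
  if (!is.null(weights) && !is.null(log_posterior)) {
    stop("supply weights or log_posterior, not both")
  }
  if (!is.null(weights)) {
    if (length(weights) != n) stop("weights length must match ensemble size")
    if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
      stop("weights must be nonnegative, finite, with positive sum")
    }
    w <- weights / sum(weights)
  } else if (!is.null(log_posterior)) {
    if (length(log_posterior) != n) {
      stop("log_posterior length must match ensemble size")
    }
    w <- softmax_weights(log_posterior)
  } else {
    w <- rep(1 / n, n)
  }
  structure(list(values = values,
                 log_posterior = if (is.null(log_posterior))
                   rep(NA_real_, n) else as.numeric(log_posterior),
                 weights = w),
            class = "parameter_ensemble")
}

## Overflow-safe conversion of log-posteriors to normalized weights.
softmax_weights <- function(log_posterior) {
  lp <- as.numeric(log_posterior)
  if (any(is.na(lp))) stop("log_posterior contains NA")
  e <- exp(lp - max(lp))
  e / sum(e)
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat("parameter_ensemble:", nrow(x$values), "vectors x",
      ncol(x$values), "parameters;",
      if (all(abs(x$weights - x$weights[1]) < 1e-15)) "uniform"
      else "non-uniform", "weights\n")
  invisible(x)
}

#' @export
length.parameter_ensemble <- function(x) nrow(x$values)

#' Extract one member of an ensemble as a parameter vector
#'
#' @param ensemble A [parameter_ensemble()].
#' @param i Row index.
#' @return A [parameter_vector()].
#' @export
ensemble_member <- function(ensemble, i) {
  parameter_vector(ensemble$values[i, ],
                   log_posterior = ensemble$log_posterior[i],
                   weight = ensemble$weights[i])
}

#' Read a parameter ensemble from disk
#'
#' Delimited text (one column per parameter, optional `log_posterior`
#' column) or HDF5 (datasets `values`, `parameter_names`, optional
#' `log_posterior`; requires the rhdf5 package). When a `log_posterior`
#' column is present it is converted to normalized weights by max-subtracted
#' exponentiation.
#'
#' @param path File path; format chosen by extension (`.h5`/`.hdf5` vs
#'   delimited text).
#' @param parameters Optional character vector of required parameter names;
#'   an error names any missing column.
#' @param sep Field separator for text files (default tab).
#' @return A [parameter_ensemble()].
#' @export
read_ensemble <- function(path, parameters = NULL, sep = "\t") {
  if (!file.exists(path)) stop("ensemble file not found: ", path)
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("the rhdf5 package is required to read HDF5 ensembles")
    }
    values <- t(rhdf5::h5read(path, "values"))
    colnames(values) <- as.character(rhdf5::h5read(path, "parameter_names"))
    lp <- tryCatch(as.numeric(rhdf5::h5read(path, "log_posterior")),
                   error = function(e) NULL)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE)
    lp <- if ("log_posterior" %in% names(df)) df$log_posterior else NULL
    df <- df[setdiff(names(df), "log_posterior")]
    values <- as.matrix(df)
  }
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, colnames(values))
    if (length(missing)) {
      stop("ensemble is missing parameter column(s): ",
           paste(missing, collapse = ", "))
    }
    values <- values[, parameters, drop = FALSE]
  }
  if (anyNA(values)) stop("ensemble contains NA rate values")
  if (any(values <= 0)) stop("ensemble contains non-positive rate values")
  parameter_ensemble(values, log_posterior = lp)
}

#' Write a parameter ensemble to disk
#'
#' Inverse of [read_ensemble()]; the `log_posterior` column is written when
#' any member has one.
#'
#' @param ensemble A [parameter_ensemble()].
#' @param path Output path; `.h5`/`.hdf5` extension selects HDF5.
#' @param sep Field separator for text output.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, sep = "\t") {
  has_lp <- !all(is.na(ensemble$log_posterior))
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("the rhdf5 package is required to write HDF5 ensembles")
    }
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(t(ensemble$values), path, "values")
    rhdf5::h5write(colnames(ensemble$values), path, "parameter_names")
    if (has_lp) rhdf5::h5write(ensemble$log_posterior, path, "log_posterior")
    rhdf5::h5closeAll()
  } else {
    df <- as.data.frame(ensemble$values)
    if (has_lp) df$log_posterior <- ensemble$log_posterior
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
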