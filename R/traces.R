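#' Set of response time traces on a common grid
#'
#' The estimator's input and the simulator's output: N nonnegative response
#' traces observed on a shared, strictly increasing time grid (hours).
#'
#' @param time Strictly increasing numeric vector of d >= 4 time points.
#' @param traces Numeric matrix (d x N) or data frame of trace columns.
#' @param lambda_d_known Optional known decay/dilution rate (per hour); when
#'   supplied, fits use fixed-lambda_d mode by default.
#' @return An object of class `"time_trace_set"`: list with `time` (length d),
#'   `traces` (d x N matrix), `lambda_d_known` (or `NULL`).
#' @export
time_trace_set <- function(time, traces, lambda_d_known = NULL) {
  time <- as.numeric(time)
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  if (length(time) < 4L) stop("need at least 4 time points")
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing")
  if (nrow(traces) != length(time))
    stop(sprintf("traces have %d rows but the grid has %d time points",
                 nrow(traces), length(time)))
  if (ncol(traces) < 1L) stop("need at least one trace")
  if (any(!is.finite(traces))) stop("traces contain non-finite values")
  if (!is.null(lambda_d_known)) stopifnot(lambda_d_known > 0)
  if (is.null(colnames(traces)))
    colnames(traces) <- sprintf("trace_%03d", seq_len(ncol(traces)))
  structure(list(time = time, traces = traces, lambda_d_known = lambda_d_known),
            class = "time_trace_set")
}

#' @export
print.time_trace_set <- function(x, ...) {
  cat(sprintf("time_trace_set: %d traces on %d time points in [%g, %g] h\n",
              ncol(x$traces), length(x$time), min(x$time), max(x$time)))
  if (!is.null(x$lambda_d_known))
    cat(sprintf("  known decay rate lambda_d = %g /h\n", x$lambda_d_known))
  invisible(x)
}

#' Mean trace across the population
#' @param Y A [time_trace_set()].
#' @return Numeric vector, the pointwise mean of all traces.
#' @export
mean_trace <- function(Y) {
  stopifnot(inherits(Y, "time_trace_set"))
  rowMeans(Y$traces)
}

#' Read a trace CSV
#'
#' Expects a header row, a first column named `time` (strictly increasing,
#' hours) and one or more numeric trace columns.  Missing or non-numeric
#' cells are errors: no silent imputation.
#'
#' @param path Path to the CSV file.
#' @return A [time_trace_set()].
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stop("trace CSV needs a time column plus >= 1 trace column")
  if (tolower(names(df)[1]) != "time")
    stop(sprintf("first column must be named 'time', found '%s'", names(df)[1]))
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.character(col) || is.factor(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      stop(sprintf("non-numeric cell in column '%s', row %d", names(df)[j],
                   if (is.na(bad)) 1L else bad))
    }
    nas <- which(is.na(col))
    if (length(nas))
      stop(sprintf("missing value in column '%s', row %d", names(df)[j], nas[1]))
  }
  tm <- as.numeric(df[[1]])
  if (any(diff(tm) <= 0)) stop("'time' column must be strictly increasing")
  time_trace_set(tm, as.matrix(df[-1]))
}

#' Write a trace CSV
#' @param Y A [time_trace_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(Y, path) {
  stopifnot(inherits(Y, "time_trace_set"))
  df <- data.frame(time = Y$time, Y$traces, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
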