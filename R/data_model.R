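#' Construct a right-censored survival dataset
#'
#' The container used throughout the package: one row per patient, a numeric
#' covariate matrix, an observed time `U = min(T, C)` and an event indicator
#' `delta` (1 = the endpoint was observed at `U`, 0 = the patient is censored
#' at `U` and the true event time is only known to exceed it). The latent true
#' and censoring times are never stored; only their observable summary is.
#'
#' @param features numeric matrix (or data frame of numerics), one row per
#'   patient, one column per covariate. Must be free of non-finite values.
#' @param time nonnegative numeric vector of observed times.
#' @param event event indicators, each 0 (censored) or 1 (event).
#' @param feature_names optional character vector of covariate labels;
#'   defaults to the column names of `features` or `x1 ... xd`.
#' @param require_events if `TRUE` (default) at least one event is required,
#'   as every downstream fit needs one.
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `features` (numeric matrix), `time`, `event` (integer), `feature_names`
#'   and `t_max` (the maximum observed time over all records).
#' @export
survival_dataset <- function(features, time, event, feature_names = NULL,
                             require_events = TRUE) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, ncol = 1L)
  storage.mode(features) <- "double"
  n <- nrow(features)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != n || length(event) != n) {
    stop("`features`, `time` and `event` must describe the same number of records",
         call. = FALSE)
  }
  if (n < 1L) stop("dataset must contain at least one record", call. = FALSE)
  bad <- which(!is.finite(time) | time < 0)
  if (length(bad)) {
    stop(sprintf("invalid observed time at row(s) %s: times must be finite and >= 0",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("invalid event indicator at row(s) %s: must be 0 or 1",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (anyNA(features) || any(!is.finite(features))) {
    bad <- which(apply(features, 1L, function(r) any(!is.finite(r))))
    stop(sprintf("non-finite covariate value at row(s) %s (missing values are rejected, not imputed)",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (require_events && sum(event) == 0) {
    stop("dataset contains no events (all records censored); model fitting requires at least one event",
         call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(features)))
  }
  if (length(feature_names) != ncol(features)) {
    stop("`feature_names` length must equal the number of feature columns", call. = FALSE)
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, time = time, event = as.integer(event),
         feature_names = feature_names, t_max = max(time)),
    class = "survival_dataset"
  )
}

#' Number of records / features in a survival dataset
#' @param d a `survival_dataset`
#' @return integer count
#' @export
n_records <- function(d) length(d$time)

#' @rdname n_records
#' @export
n_features <- function(d) ncol(d$features)

#' Read a right-censored survival dataset from CSV
#'
#' Expects a header row, one patient per row, UTF-8, comma-delimited. The
#' named time and event columns are extracted; every remaining numeric column
#' is treated as a covariate.
#'
#' @param path CSV file path.
#' @param time_column,event_column column names holding the observed time and
#'   the 0/1 event indicator (defaults `"time"`, `"event"`).
#' @param require_events require at least one event (default `TRUE`).
#' @return a [survival_dataset()]
#' @export
read_survival_csv <- function(path, time_column = "time", event_column = "event",
                              require_events = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  for (col in c(time_column, event_column)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not present in %s", col, path), call. = FALSE)
    }
  }
  feat_cols <- setdiff(names(df), c(time_column, event_column))
  numeric_ok <- vapply(df[feat_cols], is.numeric, logical(1))
  feat_cols <- feat_cols[numeric_ok]
  if (!length(feat_cols)) stop("no numeric feature columns found", call. = FALSE)
  survival_dataset(as.matrix(df[feat_cols]), df[[time_column]], df[[event_column]],
                   feature_names = feat_cols, require_events = require_events)
}

#' Write a survival dataset to CSV
#'
#' Inverse of [read_survival_csv()]: features, then the time and event
#' columns, written with full double precision so a round trip reproduces the
#' data bit-for-bit.
#'
#' @param d a `survival_dataset`
#' @param path output file path
#' @param time_column,event_column column names to use
#' @return `path`, invisibly
#' @export
write_survival_csv <- function(d, path, time_column = "time", event_column = "event") {
  df <- as.data.frame(d$features)
  df[[time_column]] <- d$time
  df[[event_column]] <- d$event
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize a survival dataset
#'
#' @param d a `survival_dataset`
#' @return list with `n`, `d` (feature count), `n_events`, `event_rate`
#'   (fraction of records with an observed event), and `t_max`.
#' @export
summarize_dataset <- function(d) {
  stopifnot(inherits(d, "survival_dataset"))
  list(n = n_records(d), d = n_features(d),
       n_events = sum(d$event),
       event_rate = sum(d$event) / n_records(d),
       t_max = d$t_max)
}

#' @export
summary.survival_dataset <- function(object, ...) {
  s <- summarize_dataset(object)
  structure(s, class = "summary.survival_dataset")
}

#' @export
print.summary.survival_dataset <- function(x, ...) {
  cat(sprintf("Right-censored survival dataset: %d records, %d features\n", x$n, x$d))
  cat(sprintf("  events: %d (event rate %.3f), t_max = %g\n",
              x$n_events, x$event_rate, x$t_max))
  invisible(x)
}

#' @export
print.survival_dataset <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' @export
as.data.frame.survival_dataset <- function(x, ...) {
  df <- as.data.frame(x$features)
  df$time <- x$time
  df$event <- x$event
  df
}

# Return a copy of `d` with record i's observed time replaced. Event
# indicators are never touched: a transduced censored record stays censored
# for any learner that uses the indicator.
replace_time <- function(d, i, new_time) {
  d$time[i] <- new_time
  d$t_max <- max(d$time)
  d
}

#' Feature standardization
#'
#' Computes per-column centering/scaling on one (training) dataset and applies
#' it to any dataset sharing the schema. Columns with zero variance keep scale
#' 1 so they pass through unchanged.
#'
#' @param d a `survival_dataset` to learn the scaling from
#' @return a list with `center` and `scale` vectors, class `feature_scaling`
#' @export
feature_scaling <- function(d) {
  ctr <- colMeans(d$features)
  scl <- apply(d$features, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  structure(list(center = ctr, scale = scl), class = "feature_scaling")
}

#' @param scaling a `feature_scaling`
#' @rdname feature_scaling
#' @export
apply_scaling <- function(scaling, d) {
  stopifnot(inherits(scaling, "feature_scaling"))
  d$features <- sweep(sweep(d$features, 2L, scaling$center, "-"),
                      2L, scaling$scale, "/")
  d
}
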