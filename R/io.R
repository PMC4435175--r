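#' Construct a raw triaxial accelerometer signal
#'
#' A `raw_signal` holds a gravity-inclusive triaxial acceleration trace
#' sampled at a nominal rate. Time must be strictly increasing and the median
#' inter-sample interval must agree with `1/rate_hz` to within 5%, so that
#' index-based windowing is valid.
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param ax,ay,az Acceleration per axis in m/s^2 (gravity included).
#' @param rate_hz Nominal sampling frequency in Hz.
#' @return An object of class `raw_signal` with fields `t`, `ax`, `ay`, `az`,
#'   `rate_hz`.
#' @export
raw_signal <- function(t, ax, ay, az, rate_hz) {
  t <- as.numeric(t); ax <- as.numeric(ax)
  ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(t)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("raw_signal: channels must have equal length", call. = FALSE)
  if (n == 0) stop("raw_signal: empty signal", call. = FALSE)
  if (!all(is.finite(c(t, ax, ay, az))))
    stop("raw_signal: all values must be finite", call. = FALSE)
  if (n > 1 && any(diff(t) <= 0))
    stop("raw_signal: time must be strictly increasing", call. = FALSE)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0)
    stop("raw_signal: rate_hz must be a positive scalar", call. = FALSE)
  if (n > 1) {
    dt <- stats::median(diff(t))
    if (abs(dt - 1 / rate_hz) > 0.05 / rate_hz)
      stop("raw_signal: median sampling interval is not within 5% of 1/rate_hz",
           call. = FALSE)
  }
  structure(list(t = t, ax = ax, ay = ay, az = az, rate_hz = rate_hz),
            class = "raw_signal")
}

#' @export
length.raw_signal <- function(x) length(x$t)

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %d samples @ %g Hz, %.2f s\n",
              length(x$t), x$rate_hz, diff(range(x$t))))
  invisible(x)
}

#' @export
as.data.frame.raw_signal <- function(x, ...) {
  data.frame(t = x$t, ax = x$ax, ay = x$ay, az = x$az)
}

#' Read a raw accelerometer CSV
#'
#' Expects a header `t,ax,ay,az` with time in seconds and acceleration in
#' m/s^2. Rows containing non-finite values are dropped with a warning.
#'
#' @param path Path to the CSV file.
#' @param rate_hz Nominal sampling frequency of the recording in Hz.
#' @return A [raw_signal()].
#' @export
read_raw_csv <- function(path, rate_hz) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("read_raw_csv: file must have columns t,ax,ay,az", call. = FALSE)
  ok <- Reduce(`&`, lapply(df[need], is.finite))
  if (!all(ok)) {
    warning(sprintf("read_raw_csv: dropping %d rows with non-finite values",
                    sum(!ok)))
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) > 1 && any(diff(df$t) <= 0))
    stop("read_raw_csv: time column is not strictly increasing", call. = FALSE)
  raw_signal(df$t, df$ax, df$ay, df$az, rate_hz)
}

#' Write a raw signal to CSV
#'
#' Inverse of [read_raw_csv()]; values round-trip exactly (full double
#' precision, decimal-point locale-independent formatting).
#'
#' @param signal A [raw_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(signal, path) {
  stopifnot(inherits(signal, "raw_signal"))
  df <- as.data.frame(signal)
  cols <- lapply(df, function(v) formatC(v, digits = 17, format = "g"))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a labeled feature table
#'
#' One row per time window, one named column per statistic, plus an activity
#' label per row.
#'
#' @param features Numeric matrix or data frame (n windows x m statistics)
#'   with unique column names.
#' @param labels Activity label per row (coerced to character).
#' @return An object of class `feature_table` with fields `features` (matrix),
#'   `labels` (character) and `class_set` (sorted unique labels).
#' @export
feature_table <- function(features, labels) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stop("feature_table: one label per feature row required", call. = FALSE)
  if (nrow(features) < 1) stop("feature_table: empty table", call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("S", seq_len(ncol(features)))
  if (anyDuplicated(colnames(features)))
    stop("feature_table: statistic names must be unique", call. = FALSE)
  structure(list(features = features, labels = labels,
                 class_set = sort(unique(labels))),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d windows x %d statistics, %d classes (%s)\n",
              nrow(x$features), ncol(x$features), length(x$class_set),
              paste(x$class_set, collapse = ", ")))
  invisible(x)
}

#' Read a feature table in the UCI-HAR two-file layout
#'
#' The feature matrix and the labels live in separate files: one window per
#' row, statistic values separated by whitespace or commas (both dialects are
#' detected), and one label per line in the labels file. Integer labels are
#' kept as their character form.
#'
#' @param features_path Path to the feature matrix file.
#' @param labels_path Path to the one-label-per-line file.
#' @param statistic_names Optional column names; defaults to `S1..Sm`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(features_path, labels_path,
                               statistic_names = NULL) {
  first <- readLines(features_path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  feats <- as.matrix(utils::read.table(features_path, sep = sep,
                                       header = FALSE,
                                       strip.white = TRUE))
  labels <- trimws(readLines(labels_path))
  labels <- labels[nzchar(labels)]
  if (nrow(feats) != length(labels))
    stop(sprintf(
      "read_feature_table: %d feature rows but %d labels (files misaligned)",
      nrow(feats), length(labels)), call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("read_feature_table: at least 2 classes are required", call. = FALSE)
  if (!is.null(statistic_names)) colnames(feats) <- statistic_names
  else colnames(feats) <- paste0("S", seq_len(ncol(feats)))
  feature_table(feats, labels)
}

#' Write a feature table in the UCI-HAR two-file layout
#'
#' @param table A [feature_table()].
#' @param features_path,labels_path Output paths.
#' @param sep Field separator for the feature matrix (`" "` or `","`).
#' @return Invisibly, `c(features_path, labels_path)`.
#' @export
write_feature_table <- function(table, features_path, labels_path, sep = " ") {
  stopifnot(inherits(table, "feature_table"))
  utils::write.table(format(table$features, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     features_path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(table$labels, labels_path)
  invisible(c(features_path, labels_path))
}

MODEL_SCHEMA_VERSION <- "1.0"

num_to_json <- function(x) {
  out <- as.list(x)
  lapply(out, function(v) {
    if (is.numeric(v) && length(v) == 1 && !is.finite(v))
      if (v > 0) "+inf" else "-inf"
    else v
  })
}

bound_from_json <- function(x) {
  vapply(x, function(v) {
    if (identical(v, "+inf") || identical(v, "inf")) Inf
    else if (identical(v, "-inf")) -Inf
    else as.numeric(v)
  }, numeric(1))
}

#' Save an Ameva model as versioned JSON
#'
#' The serialized document carries only what recognition needs: per-statistic
#' interval bounds, the activity-interval likelihoods, class names, and the
#' Ameva coefficients — a payload small enough to transmit between device and
#' server. Infinite interval bounds are written as the strings `"-inf"` /
#' `"+inf"`.
#'
#' @param model An [ameva_model] as returned by [train_ameva()].
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ameva_model"))
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    class_names = model$class_names,
    selected_statistics = model$selected_statistics,
    selection_threshold = model$selection_threshold,
    novelty_threshold = model$novelty_threshold,
    metadata = model$metadata,
    statistics = lapply(names(model$discretization), function(p) {
      iset <- model$discretization[[p]]
      u <- model$activity_interval$u_norm[[p]]
      uraw <- model$activity_interval$u_raw[[p]]
      list(name = p,
           lower = lapply(iset$lower, function(v)
             if (is.finite(v)) v else "-inf"),
           upper = lapply(iset$upper, function(v)
             if (is.finite(v)) v else "+inf"),
           ameva_value = model$ameva_values[[p]],
           u_raw = uraw,
           u_norm = u)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load an Ameva model from JSON
#'
#' @param path Path to a document written by [save_model()].
#' @return An [ameva_model].
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("load_model: cannot parse model file: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(doc$schema_version, MODEL_SCHEMA_VERSION))
    stop(sprintf("load_model: schema version %s not supported (expected %s)",
                 doc$schema_version %||% "<missing>", MODEL_SCHEMA_VERSION),
         call. = FALSE)
  class_names <- unlist(doc$class_names)
  stats <- doc$statistics
  names(stats) <- vapply(stats, `[[`, "", "name")
  discretization <- lapply(stats, function(s) {
    lower <- bound_from_json(s$lower)
    upper <- bound_from_json(s$upper)
    interval_set(s$name, cuts = upper[-length(upper)],
                 ameva_value = as.numeric(s$ameva_value))
  })
  to_mat <- function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
    colnames(m) <- class_names
    rownames(m) <- paste0("L", seq_len(nrow(m)))
    m
  }
  u_raw <- lapply(stats, function(s) to_mat(s$u_raw))
  u_norm <- lapply(stats, function(s) to_mat(s$u_norm))
  ameva_values <- vapply(stats, function(s) as.numeric(s$ameva_value),
                         numeric(1))
  new_ameva_model(
    discretization = discretization,
    activity_interval = list(u_raw = u_raw, u_norm = u_norm,
                             class_names = class_names),
    class_names = class_names,
    ameva_values = ameva_values,
    selected_statistics = unlist(doc$selected_statistics),
    selection_threshold = as.numeric(doc$selection_threshold %||% 0),
    novelty_threshold = as.numeric(doc$novelty_threshold %||% 0.2),
    metadata = doc$metadata %||% list())
}
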