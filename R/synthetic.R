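#' Specification of a synthetic activity
#'
#' Describes the accelerometer signature of one activity: a fundamental
#' cadence with harmonic amplitudes riding on a gravity offset plus white
#' noise, and (optionally) per-statistic Gaussian parameters for direct
#' feature-table generation. Cyclic activities (walking ~1.8 Hz cycles) get
#' nonzero cadence and harmonics; static postures get cadence 0 and small
#' noise so their windows fall below the 0.3 duty-cycle variance threshold.
#'
#' @param name Activity name.
#' @param cadence_hz Fundamental cycle frequency in Hz (0 for static).
#' @param harmonics Amplitudes of the harmonics in m/s^2 (element h is the
#'   amplitude at `h * cadence_hz`).
#' @param gravity Unit-ish orientation vector of gravity in device axes.
#' @param noise_sd White-noise standard deviation in m/s^2 (>= 0).
#' @param feature_means,feature_sds Optional named per-statistic Gaussian
#'   parameters used by [generate_feature_table()].
#' @return An object of class `activity_spec`.
#' @export
activity_spec <- function(name, cadence_hz = 0, harmonics = numeric(0),
                          gravity = c(0, 0, 1), noise_sd = 0.05,
                          feature_means = NULL, feature_sds = NULL) {
  if (noise_sd < 0) stop("activity_spec: noise_sd must be >= 0",
                         call. = FALSE)
  if (cadence_hz < 0) stop("activity_spec: cadence_hz must be >= 0",
                           call. = FALSE)
  structure(list(name = name, cadence_hz = cadence_hz,
                 harmonics = harmonics,
                 gravity = gravity / sqrt(sum(gravity^2)),
                 noise_sd = noise_sd,
                 feature_means = feature_means, feature_sds = feature_sds),
            class = "activity_spec")
}

#' Built-in synthetic activity catalogue
#'
#' Cadences follow typical human rates (walking ~1.8 Hz, running ~2.8 Hz,
#' stair climbs a little slower than level walking); static postures differ
#' by gravity orientation and have noise small enough that their magnitude
#' variance stays below the duty-cycle threshold, while cyclic activities
#' stay well above it.
#'
#' @return Named list of [activity_spec()]s.
#' @export
default_activity_specs <- function() {
  specs <- list(
    activity_spec("walking", cadence_hz = 1.8, harmonics = c(3, 1.2, 0.4),
                  noise_sd = 0.3),
    activity_spec("running", cadence_hz = 2.8, harmonics = c(6, 2.5, 0.8),
                  noise_sd = 0.5),
    activity_spec("upstairs", cadence_hz = 1.5, harmonics = c(2.5, 1.0, 0.3),
                  noise_sd = 0.3),
    activity_spec("downstairs", cadence_hz = 1.6, harmonics = c(2.8, 0.9, 0.3),
                  noise_sd = 0.3),
    activity_spec("sitting", cadence_hz = 0, gravity = c(0.3, 0, 0.95),
                  noise_sd = 0.05),
    activity_spec("standing", cadence_hz = 0, gravity = c(0, 0, 1),
                  noise_sd = 0.05),
    activity_spec("lying", cadence_hz = 0, gravity = c(1, 0, 0),
                  noise_sd = 0.05),
    activity_spec("idle", cadence_hz = 0, gravity = c(0, 0, 1),
                  noise_sd = 0.02))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Generate a synthetic accelerometer signal
#'
#' Sum of a gravity offset (9.81 m/s^2 along the spec's orientation),
#' harmonics at multiples of the cadence (full amplitude on the vertical
#' axis, reduced copies on the horizontal axes, with fixed phase offsets),
#' and white Gaussian noise. A pure function of `(spec, duration, rate,
#' seed)`.
#'
#' @param spec An [activity_spec()].
#' @param duration_s Duration in seconds (> 0).
#' @param rate_hz Sampling rate in Hz.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [raw_signal()].
#' @export
generate_signal <- function(spec, duration_s, rate_hz = 50, seed = NULL) {
  stopifnot(inherits(spec, "activity_spec"))
  if (duration_s <= 0) stop("generate_signal: duration_s must be > 0",
                            call. = FALSE)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  g <- 9.81 * spec$gravity
  base <- list(ax = rep(g[1], n), ay = rep(g[2], n), az = rep(g[3], n))
  if (spec$cadence_hz > 0 && length(spec$harmonics)) {
    for (h in seq_along(spec$harmonics)) {
      ph <- (h - 1) * pi / 3  # fixed per-harmonic phase offsets
      osc <- spec$harmonics[h] * sin(2 * pi * h * spec$cadence_hz * t + ph)
      base$az <- base$az + osc
      base$ax <- base$ax + 0.4 * spec$harmonics[h] *
        sin(2 * pi * h * spec$cadence_hz * t + ph + pi / 4)
      base$ay <- base$ay + 0.2 * osc
    }
  }
  with_local_seed(seed, {
    base$ax <- base$ax + stats::rnorm(n, 0, spec$noise_sd)
    base$ay <- base$ay + stats::rnorm(n, 0, spec$noise_sd)
    base$az <- base$az + stats::rnorm(n, 0, spec$noise_sd)
  })
  raw_signal(t, base$ax, base$ay, base$az, rate_hz)
}

#' Generate a labeled feature table directly from class distributions
#'
#' Draws each statistic of each window from the per-class Gaussian recorded
#' in the specs (`feature_means` / `feature_sds`), bypassing signal synthesis
#' so classifier behavior can be studied independently of feature-extraction
#' choices. Classes are balanced and the result is a pure function of
#' `(specs, windows_per_class, seed)`.
#'
#' @param specs List of [activity_spec()]s (>= 2) carrying `feature_means`
#'   and `feature_sds` with identical statistic names.
#' @param windows_per_class Rows generated per class.
#' @param seed Integer seed.
#' @return A [feature_table()] with `length(specs) * windows_per_class` rows.
#' @export
generate_feature_table <- function(specs, windows_per_class = 200, seed = 1) {
  if (length(specs) < 2)
    stop("generate_feature_table: at least 2 specs are required",
         call. = FALSE)
  stat_names <- names(specs[[1]]$feature_means)
  if (is.null(stat_names))
    stop("generate_feature_table: specs must carry named feature_means",
         call. = FALSE)
  with_local_seed(seed, {
    rows <- lapply(specs, function(sp) {
      mu <- sp$feature_means[stat_names]
      sdv <- sp$feature_sds[stat_names]
      m <- vapply(stat_names, function(s)
        stats::rnorm(windows_per_class, mu[[s]], sdv[[s]]),
        numeric(windows_per_class))
      if (windows_per_class == 1) m <- matrix(m, nrow = 1,
                                              dimnames = list(NULL,
                                                              stat_names))
      m
    })
    feats <- do.call(rbind, rows)
    colnames(feats) <- stat_names
    labels <- rep(vapply(specs, `[[`, "", "name"),
                  each = windows_per_class)
    feature_table(feats, labels)
  })
}
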