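#' Segment a raw signal into overlapping time windows
#'
#' Windows are full-length, closed-open in time `[start, start + window_s)`,
#' start at multiples of `step = window_s - overlap_s`, and are aligned by
#' sample index (no timestamp interpolation), so segmentation is
#' deterministic. Trailing samples that do not fill a window are dropped. The
#' window must be long enough to contain at least one activity cycle; the
#' defaults (4 s window, 1 s overlap) satisfy this for ordinary human
#' movement.
#'
#' @param signal A [raw_signal()].
#' @param window_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (`0 <= overlap_s < window_s`).
#' @return List of `ameva_window` objects (fields `start_s`, `t`, `ax`, `ay`,
#'   `az`, `rate_hz`); empty with a warning if the signal is shorter than one
#'   window.
#' @export
segment_windows <- function(signal, window_s = 4, overlap_s = 1) {
  stopifnot(inherits(signal, "raw_signal"))
  if (overlap_s < 0 || overlap_s >= window_s)
    stop("segment_windows: need 0 <= overlap_s < window_s", call. = FALSE)
  n <- length(signal$t)
  win_n <- round(window_s * signal$rate_hz)
  step_n <- round((window_s - overlap_s) * signal$rate_hz)
  if (n < win_n) {
    warning("segment_windows: signal shorter than one window")
    return(list())
  }
  starts <- seq(1L, n - win_n + 1L, by = step_n)
  lapply(starts, function(s) {
    idx <- s:(s + win_n - 1L)
    structure(list(start_s = signal$t[s], t = signal$t[idx],
                   ax = signal$ax[idx], ay = signal$ay[idx],
                   az = signal$az[idx], rate_hz = signal$rate_hz),
              class = "ameva_window")
  })
}

window_magnitude <- function(window) {
  sqrt(window$ax^2 + window$ay^2 + window$az^2)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Removes carry-vibration noise above `cutoff_hz` from every channel using a
#' Butterworth design applied forward and backward (zero phase), so activity
#' cycles are not shifted across window boundaries. Output length equals
#' input length.
#'
#' @param signal A [raw_signal()].
#' @param cutoff_hz Cutoff frequency, `0 < cutoff_hz < rate_hz / 2`.
#' @param order Filter order (>= 1); default 3.
#' @return A filtered [raw_signal()].
#' @export
lowpass_filter <- function(signal, cutoff_hz = 20, order = 3) {
  stopifnot(inherits(signal, "raw_signal"))
  nyq <- signal$rate_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("lowpass_filter: cutoff must lie in (0, rate_hz/2)", call. = FALSE)
  if (order < 1) stop("lowpass_filter: order must be >= 1", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # mean removal keeps DC exact; odd-reflection padding suppresses the
  # forward-backward edge transient
  filt <- function(x) {
    n <- length(x)
    mu <- mean(x)
    x <- x - mu
    p <- min(n - 1L, max(24L, 6L * (order + 1L)))
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    y <- as.numeric(signal::filtfilt(bf, xp))
    y[(p + 1):(p + n)] + mu
  }
  raw_signal(signal$t, filt(signal$ax), filt(signal$ay), filt(signal$az),
             signal$rate_hz)
}

#' Default per-window statistic set
#'
#' Statistic names follow the pattern `<stat>_<channel>` with channels `ax`,
#' `ay`, `az` and `mag` (the magnitude `sqrt(ax^2 + ay^2 + az^2)`, included
#' so the set is robust to device orientation), plus the channel-free
#' `corr_xy`, `corr_xz`, `corr_yz` (pairwise axis correlations) and
#' `tilt_angle` (angle between the window's mean acceleration vector and the
#' gravity reference (0, 0, 1), radians).
#'
#' @param channels Channels to expand the per-channel statistics over.
#' @param stats Per-channel statistic names; any subset of `mean`, `sd`,
#'   `mad` (median absolute deviation), `max`, `min`, `energy` (mean of
#'   squared samples), `iqr`, `entropy` (spectral entropy), `skewness`,
#'   `kurtosis`, `jerk_mean` (mean first difference scaled by the sampling
#'   rate).
#' @return Character vector of statistic names.
#' @export
default_statistic_set <- function(channels = c("ax", "ay", "az", "mag"),
                                  stats = c("mean", "sd", "mad", "max", "min",
                                            "energy", "iqr", "entropy",
                                            "skewness", "kurtosis",
                                            "jerk_mean")) {
  c(as.vector(outer(stats, channels, paste, sep = "_")),
    "corr_xy", "corr_xz", "corr_yz", "tilt_angle")
}

spectral_entropy <- function(x) {
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  p <- p[2:(floor(length(x) / 2) + 1)]
  s <- sum(p)
  if (s <= 0) return(0)
  p <- p[p > 0] / s
  -sum(p * log(p))
}

safe_cor <- function(a, b, flags, name) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(v = 0, flags = c(flags, name)))
  list(v = stats::cor(a, b), flags = flags)
}

#' Compute the statistic vector of one window
#'
#' Evaluates each named statistic on the configured channel (see
#' [default_statistic_set()] for the naming scheme). Statistics that are
#' undefined on a zero-variance window (correlation, skewness, kurtosis)
#' return 0, and the affected names are recorded in the `"degenerate"`
#' attribute of the result.
#'
#' @param window An `ameva_window` from [segment_windows()].
#' @param statistic_set Character vector of statistic names.
#' @return Named numeric vector, all finite.
#' @export
compute_statistics <- function(window, statistic_set = default_statistic_set()) {
  stopifnot(inherits(window, "ameva_window"))
  if (!length(window$ax)) stop("compute_statistics: empty window",
                               call. = FALSE)
  chans <- list(ax = window$ax, ay = window$ay, az = window$az,
                mag = window_magnitude(window))
  flags <- character(0)
  out <- numeric(length(statistic_set))
  names(out) <- statistic_set
  for (nm in statistic_set) {
    if (nm %in% c("corr_xy", "corr_xz", "corr_yz")) {
      pair <- switch(nm, corr_xy = c("ax", "ay"), corr_xz = c("ax", "az"),
                     corr_yz = c("ay", "az"))
      r <- safe_cor(chans[[pair[1]]], chans[[pair[2]]], flags, nm)
      out[nm] <- r$v; flags <- r$flags
      next
    }
    if (nm == "tilt_angle") {
      v <- c(mean(window$ax), mean(window$ay), mean(window$az))
      nv <- sqrt(sum(v^2))
      out[nm] <- if (nv == 0) 0 else acos(max(-1, min(1, v[3] / nv)))
      next
    }
    parts <- regmatches(nm, regexpr("_(ax|ay|az|mag)$", nm))
    if (!length(parts))
      stop("compute_statistics: unknown statistic name: ", nm, call. = FALSE)
    chan <- sub("^_", "", parts)
    stat <- sub("_(ax|ay|az|mag)$", "", nm)
    x <- chans[[chan]]
    out[nm] <- switch(stat,
      mean = mean(x),
      sd = stats::sd(x),
      mad = stats::mad(x),
      max = max(x),
      min = min(x),
      energy = mean(x^2),
      iqr = stats::IQR(x),
      entropy = spectral_entropy(x),
      skewness = if (stats::sd(x) == 0) {
        flags <- c(flags, nm); 0
      } else e1071::skewness(x),
      kurtosis = if (stats::sd(x) == 0) {
        flags <- c(flags, nm); 0
      } else e1071::kurtosis(x),
      jerk_mean = if (length(x) < 2) 0 else mean(diff(x)) * window$rate_hz,
      stop("compute_statistics: unknown statistic name: ", nm, call. = FALSE))
  }
  if (!all(is.finite(out))) {
    flags <- c(flags, names(out)[!is.finite(out)])
    out[!is.finite(out)] <- 0
  }
  if (length(flags)) attr(out, "degenerate") <- unique(flags)
  out
}

#' Extract a feature table from a raw signal
#'
#' Filters, segments and computes the statistic vector of every window — the
#' signal-to-table half of the pipeline.
#'
#' @param signal A [raw_signal()].
#' @param window_s,overlap_s Segmentation parameters (defaults 4 s / 1 s).
#' @param statistic_set Statistic names, see [compute_statistics()].
#' @param labels Optional label per window (recycled if length 1). When
#'   omitted, labels default to `"unlabeled"`.
#' @param cutoff_hz,filter_order Low-pass settings; `cutoff_hz = NULL` skips
#'   filtering.
#' @return A [feature_table()].
#' @export
features_from_signal <- function(signal, window_s = 4, overlap_s = 1,
                                 statistic_set = default_statistic_set(),
                                 labels = NULL, cutoff_hz = 20,
                                 filter_order = 3) {
  if (!is.null(cutoff_hz))
    signal <- lowpass_filter(signal, cutoff_hz, filter_order)
  wins <- segment_windows(signal, window_s, overlap_s)
  if (!length(wins))
    stop("features_from_signal: signal shorter than one window",
         call. = FALSE)
  feats <- do.call(rbind, lapply(wins, compute_statistics,
                                 statistic_set = statistic_set))
  labels <- labels %||% "unlabeled"
  if (length(labels) == 1) labels <- rep(labels, length(wins))
  if (length(labels) != length(wins))
    stop("features_from_signal: one label per window required", call. = FALSE)
  feature_table(feats, labels)
}

#' Cadence (activity cycles per minute) of a window
#'
#' The dominant frequency `tau` is the non-DC frequency bin with the largest
#' spectral magnitude of the magnitude channel; the cadence is
#' `z = tau * 60` cycles per minute. The resolution is one spectral bin,
#' `rate_hz / n` Hz (0.25 Hz, i.e. 15 cycles/min, for a 4 s window).
#'
#' @param window An `ameva_window` (>= 2 samples).
#' @return List of class `cadence_result`: `tau` (Hz), `cycles_per_min`, and
#'   `idle` (TRUE for an all-constant window, which yields `tau = 0`).
#' @export
cadence <- function(window) {
  stopifnot(inherits(window, "ameva_window"))
  m <- window_magnitude(window)
  n <- length(m)
  if (n < 2) stop("cadence: window must have at least 2 samples",
                  call. = FALSE)
  if (stats::sd(m) == 0)
    return(structure(list(tau = 0, cycles_per_min = 0, idle = TRUE),
                     class = "cadence_result"))
  spec <- Mod(stats::fft(m - mean(m)))
  bins <- 2:(floor(n / 2) + 1)
  freqs <- (bins - 1) * window$rate_hz / n
  tau <- freqs[which.max(spec[bins])]
  structure(list(tau = tau, cycles_per_min = tau * 60, idle = FALSE),
            class = "cadence_result")
}

#' Recognition delay of a window configuration
#'
#' `delay = window_s * 0.75 + k_device * f_cost(window_s)`: the fixed
#' fraction of the window that must elapse before a classification can be
#' produced, plus a device-dependent processing cost. `k_device` is a
#' per-device computational constant and `f_cost` the (nondecreasing)
#' complexity of discretization plus classification as a function of window
#' length.
#'
#' @param window_s Window length in seconds (> 0).
#' @param k_device Device constant (>= 0, default 0).
#' @param f_cost Nondecreasing cost function of `window_s`; default identity.
#' @return Delay in seconds.
#' @export
recognition_delay <- function(window_s, k_device = 0, f_cost = identity) {
  if (window_s <= 0) stop("recognition_delay: window_s must be > 0",
                          call. = FALSE)
  if (k_device < 0) stop("recognition_delay: k_device must be >= 0",
                         call. = FALSE)
  window_s * 0.75 + k_device * f_cost(window_s)
}
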