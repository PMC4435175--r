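#' Dynamic sampling-rate controller state
#'
#' Tracks how long the recognized activity has been stable and lowers the
#' accelerometer rate for "critical" (low-motion) activities once stability
#' exceeds the per-activity memory. Sedentary postures need only 32 Hz while
#' locomotion needs 50 Hz, so the rate map defaults to those values. On
#' prolonged stabilization the window length itself grows (by the base-2 log
#' of the modular stability count), reducing how often classification runs.
#'
#' @param sample_rate_list Named numeric map activity -> Hz.
#' @param max_memory_list Named map activity -> consecutive-window count
#'   required before the rate may change; a single number is recycled.
#' @param critical_activities Activities allowed to lower the rate.
#' @param win_size_s Initial window length in seconds.
#' @param rate_hz Initial sampling rate in Hz.
#' @param initial_activity Optional activity assumed already recognized, so
#'   the first matching step counts as a repeat.
#' @param max_win_size_s Cap on window growth in seconds (keeps the
#'   recognition delay bounded).
#' @return An object of class `sample_rate_state`.
#' @export
sample_rate_state <- function(sample_rate_list = c(sitting = 32, standing = 32,
                                                   lying = 32, walking = 50,
                                                   upstairs = 50,
                                                   downstairs = 50),
                              max_memory_list = 5,
                              critical_activities = c("sitting", "standing",
                                                      "lying"),
                              win_size_s = 4, rate_hz = 50,
                              initial_activity = NULL,
                              max_win_size_s = 30) {
  acts <- names(sample_rate_list)
  if (is.null(acts)) stop("sample_rate_state: sample_rate_list must be named",
                          call. = FALSE)
  if (length(max_memory_list) == 1 && is.null(names(max_memory_list)))
    max_memory_list <- stats::setNames(rep(max_memory_list, length(acts)),
                                       acts)
  if (!all(acts %in% names(max_memory_list)))
    stop("sample_rate_state: max_memory_list must cover every activity",
         call. = FALSE)
  structure(list(sample_rate_list = sample_rate_list,
                 max_memory_list = max_memory_list,
                 critical_activities = critical_activities,
                 count = 0L,
                 a_previous = initial_activity,
                 win_size_s = win_size_s,
                 current_rate_hz = rate_hz,
                 win_samples = rate_hz * win_size_s,
                 max_win_size_s = max_win_size_s),
            class = "sample_rate_state")
}

#' Advance the dynamic sampling-rate controller by one window
#'
#' If the recognized activity repeats, the stability count increments;
#' otherwise it resets to 0. Once a critical activity has been stable for
#' more than its memory, the rate switches to that activity's configured
#' value. When the modular stability count hits the activity's memory again
#' (every 30 windows), the window grows by `log2` of the modular count, up to
#' the configured cap.
#'
#' @param state A [sample_rate_state()].
#' @param activity Recognized activity for the current window; must be a key
#'   of the rate map.
#' @return The updated `sample_rate_state`.
#' @export
sample_rate_step <- function(state, activity) {
  stopifnot(inherits(state, "sample_rate_state"))
  if (!activity %in% names(state$sample_rate_list))
    stop("sample_rate_step: unknown activity: ", activity, call. = FALSE)
  if (!is.null(state$a_previous) && identical(activity, state$a_previous))
    state$count <- state$count + 1L
  else
    state$count <- 0L
  maxmem <- state$max_memory_list[[activity]]
  if (activity %in% state$critical_activities && state$count > maxmem) {
    state$current_rate_hz <- state$sample_rate_list[[activity]]
    state$win_samples <- state$current_rate_hz * state$win_size_s
  }
  modc <- state$count %% 30L
  if (modc == maxmem && modc > 0L) {
    state$win_size_s <- min(state$win_size_s + log2(modc),
                            state$max_win_size_s)
    state$win_samples <- state$current_rate_hz * state$win_size_s
  }
  state$a_previous <- activity
  state
}

#' Duty-cycle controller state
#'
#' When consecutive windows show almost no acceleration variance the device
#' is not being worn (e.g. lying on a table), so sensing can sleep in
#' escalating periods. The period list is ordered ascending (3 s up to 1 h)
#' so that advancing the duty index lengthens the sleep, and any movement
#' window resets the escalation.
#'
#' @param duty_cycle_periods Ordered sleep durations in milliseconds.
#' @param variance_threshold Magnitude-channel variance (m/s^2 squared) below
#'   which a window counts as idle; default 0.3.
#' @param min_windows_sleep Consecutive idle windows required before each
#'   sleep is emitted; default 5.
#' @return An object of class `duty_cycle_state`.
#' @export
duty_cycle_state <- function(duty_cycle_periods = c(3000, 10000, 60000,
                                                    300000, 600000, 1800000,
                                                    3600000),
                             variance_threshold = 0.3,
                             min_windows_sleep = 5) {
  if (is.unsorted(duty_cycle_periods))
    stop("duty_cycle_state: periods must be ascending", call. = FALSE)
  structure(list(duty_cycle_periods = duty_cycle_periods,
                 variance_threshold = variance_threshold,
                 min_windows_sleep = min_windows_sleep,
                 duty_index = 0L,
                 windows_sleep = 0L,
                 asleep_ms = 0),
            class = "duty_cycle_state")
}

#' Advance the duty-cycle controller by one window
#'
#' A window with variance strictly below the threshold is labeled idle ("no
#' device") and counted; when the count reaches `min_windows_sleep` the duty
#' index advances (capped at the last period), a sleep of the indexed period
#' is emitted, and the idle count restarts so continued stillness keeps
#' escalating. A window at or above the threshold is movement: it resets the
#' duty index and emits no sleep.
#'
#' @param state A [duty_cycle_state()].
#' @param window_variance Variance of the window's magnitude channel (>= 0).
#' @return List with `state` (updated), `sleep_ms` (0 when no sleep was
#'   emitted) and `idle` (logical).
#' @export
duty_cycle_step <- function(state, window_variance) {
  stopifnot(inherits(state, "duty_cycle_state"))
  if (window_variance < 0)
    stop("duty_cycle_step: variance must be >= 0", call. = FALSE)
  sleep_ms <- 0
  idle <- window_variance < state$variance_threshold
  if (idle) {
    state$windows_sleep <- state$windows_sleep + 1L
    if (state$windows_sleep == state$min_windows_sleep) {
      if (state$duty_index < length(state$duty_cycle_periods))
        state$duty_index <- state$duty_index + 1L
      sleep_ms <- state$duty_cycle_periods[state$duty_index]
      state$asleep_ms <- state$asleep_ms + sleep_ms
      state$windows_sleep <- 0L
    }
  } else {
    state$duty_index <- 0L
  }
  list(state = state, sleep_ms = sleep_ms, idle = idle)
}

#' Simulate a window stream through the classifier and both controllers
#'
#' Replays a schedule of activities window by window: each window is
#' synthesized from its activity's spec at the controller's current sampling
#' rate, its magnitude variance feeds the duty-cycle controller, and the
#' recognized activity (from `model`, or the true label when no model is
#' given) feeds the sampling-rate controller. The controllers only shape the
#' sensing schedule — they never alter the classification. The sampling
#' burden is compared against an always-on 50 Hz baseline.
#'
#' @param specs Named list of [activity_spec()]s covering every scheduled
#'   activity.
#' @param schedule Data frame with columns `activity` and `windows` giving
#'   the stream as consecutive runs.
#' @param window_s Window length in seconds used for synthesis (the
#'   controller's internal window growth does not feed back into synthesis).
#' @param model Optional [ameva_model] used to recognize each window from its
#'   statistic vector.
#' @param statistic_set Statistic names used when `model` is given.
#' @param srs Initial [sample_rate_state()].
#' @param dc Initial [duty_cycle_state()].
#' @param baseline_rate_hz Static baseline rate for the burden comparison.
#' @param seed Integer seed; every window's noise derives from it.
#' @return List with `events` (one row per window: activity, recognized,
#'   rate_hz, samples, variance, idle, sleep_ms, awake_fraction so far),
#'   `awake_fraction`, `samples_collected`, `baseline_samples`.
#' @export
simulate_stream <- function(specs, schedule, window_s = 4, model = NULL,
                            statistic_set = default_statistic_set(),
                            srs = sample_rate_state(),
                            dc = duty_cycle_state(),
                            baseline_rate_hz = 50, seed = 1) {
  stopifnot(is.data.frame(schedule),
            all(c("activity", "windows") %in% names(schedule)))
  acts <- rep(as.character(schedule$activity), schedule$windows)
  if (!all(acts %in% names(specs)))
    stop("simulate_stream: schedule activity without a spec", call. = FALSE)
  n <- length(acts)
  events <- data.frame(window = seq_len(n), activity = acts,
                       recognized = character(n), rate_hz = numeric(n),
                       samples = numeric(n), variance = numeric(n),
                       idle = logical(n), sleep_ms = numeric(n),
                       awake_fraction = numeric(n),
                       stringsAsFactors = FALSE)
  awake_ms <- 0
  sleep_ms_total <- 0
  samples <- 0
  for (w in seq_len(n)) {
    rate <- srs$current_rate_hz
    sig <- generate_signal(specs[[acts[w]]], duration_s = window_s,
                           rate_hz = rate, seed = seed + w)
    win <- segment_windows(sig, window_s, 0)[[1]]
    v <- stats::var(window_magnitude(win))
    rec <- if (is.null(model)) acts[w]
           else classify_window(model, compute_statistics(win,
                                                          statistic_set))$activity
    step <- duty_cycle_step(dc, v)
    dc <- step$state
    # activities outside the rate map (e.g. the idle / no-device label) are
    # the duty-cycle controller's business, not the rate controller's
    if (rec %in% names(srs$sample_rate_list))
      srs <- sample_rate_step(srs, rec)
    awake_ms <- awake_ms + window_s * 1000
    sleep_ms_total <- sleep_ms_total + step$sleep_ms
    samples <- samples + length(win$t)
    events$recognized[w] <- rec
    events$rate_hz[w] <- rate
    events$samples[w] <- length(win$t)
    events$variance[w] <- v
    events$idle[w] <- step$idle
    events$sleep_ms[w] <- step$sleep_ms
    events$awake_fraction[w] <- awake_ms / (awake_ms + sleep_ms_total)
  }
  list(events = events,
       awake_fraction = awake_ms / (awake_ms + sleep_ms_total),
       samples_collected = samples,
       baseline_samples = baseline_rate_hz * window_s * n)
}
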