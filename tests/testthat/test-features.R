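flat_signal <- function(duration_s, rate_hz = 50, level = 9.81) {
  n <- round(duration_s * rate_hz)
  raw_signal((seq_len(n) - 1) / rate_hz, rep(0, n), rep(0, n),
             rep(level, n), rate_hz)
}

# tone rides along the gravity axis so the magnitude channel oscillates at
# the tone frequency itself (a tone orthogonal to gravity would rectify to
# twice the frequency in the magnitude)
tone_signal <- function(freq, duration_s = 4, rate_hz = 50, amp = 1) {
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  raw_signal(t, amp * sin(2 * pi * freq * t), rep(0, n),
             9.81 + amp * sin(2 * pi * freq * t), rate_hz)
}

test_that("segmentation produces full-length windows on the step grid", {
  wins <- segment_windows(flat_signal(10), window_s = 4, overlap_s = 1)
  expect_length(wins, 3)
  expect_equal(vapply(wins, `[[`, numeric(1), "start_s"), c(0, 3, 6))
  expect_true(all(vapply(wins, function(w) length(w$ax), integer(1)) == 200))

  expect_warning(w0 <- segment_windows(flat_signal(3), 4, 1), "shorter")
  expect_length(w0, 0)

  # 2.56 s at 50 Hz with 50% overlap: the UCI-HAR configuration
  wins <- segment_windows(flat_signal(10.24), 2.56, 1.28)
  expect_equal(length(wins[[1]]$ax), 128)

  expect_error(segment_windows(flat_signal(10), 4, 4), "overlap")
})

test_that("window count follows floor((duration - window)/step) + 1", {
  for (dur in c(4, 5.5, 9, 12, 20)) for (win in c(2, 4)) for (ov in c(0, 1)) {
    wins <- segment_windows(flat_signal(dur), win, ov)
    expect_length(wins, floor((dur - win) / (win - ov)) + 1)
  }
})

test_that("zero-phase Butterworth keeps DC and the passband, cuts the stopband", {
  const <- flat_signal(4)
  out <- lowpass_filter(const, 20, 3)
  expect_equal(out$az, const$az, tolerance = 1e-9)
  expect_length(out$az, length(const$az))

  hi <- tone_signal(24, rate_hz = 100)
  out <- lowpass_filter(hi, 20, 3)
  expect_lt(sqrt(mean(out$ax^2)), sqrt(mean(hi$ax^2)))

  lo <- tone_signal(1)
  out <- lowpass_filter(lo, 20, 3)
  # analytic Butterworth magnitude at 1 Hz, squared for forward-backward
  gain <- (1 / sqrt(1 + (1 / 20)^(2 * 3)))^2
  got <- max(abs(out$ax[50:150])) / max(abs(lo$ax[50:150]))
  expect_equal(got, gain, tolerance = 0.01)

  expect_error(lowpass_filter(lo, 25, 3), "cutoff")
})

test_that("statistics behave on degenerate and closed-form windows", {
  const <- make_window(rep(3.2, 100))
  s <- compute_statistics(const, c("mean_ax", "sd_ax", "max_ax", "min_ax",
                                   "jerk_mean_ax", "skewness_ax", "corr_xy"))
  expect_equal(unname(s[c("mean_ax", "sd_ax", "max_ax", "min_ax",
                          "jerk_mean_ax")]), c(3.2, 0, 3.2, 3.2, 0))
  expect_equal(unname(s[["skewness_ax"]]), 0)
  expect_true(all(c("skewness_ax", "corr_xy") %in%
                    attr(s, "degenerate")))

  alt <- make_window(rep(c(-1, 1), 50))
  expect_equal(unname(compute_statistics(alt, "skewness_ax")[[1]]), 0)

  n <- 200
  sine <- make_window(sin(2 * pi * 2 * (0:(n - 1)) / 50))
  e <- compute_statistics(sine, "energy_ax")[["energy_ax"]]
  expect_equal(e, 0.5, tolerance = 2 / n)
})

test_that("statistics are shift-invariant and offset-equivariant", {
  x <- sin(2 * pi * 1.5 * (0:199) / 50) + 0.3
  w1 <- make_window(x, start_s = 0)
  w2 <- make_window(x, start_s = 12)
  set <- c("mean_ax", "sd_ax", "max_ax", "min_ax", "energy_ax", "iqr_ax",
           "entropy_ax", "skewness_ax", "kurtosis_ax", "jerk_mean_ax")
  expect_equal(compute_statistics(w1, set), compute_statistics(w2, set))

  w3 <- make_window(x + 5)
  s1 <- compute_statistics(w1, c("mean_ax", "max_ax", "min_ax"))
  s3 <- compute_statistics(w3, c("mean_ax", "max_ax", "min_ax"))
  expect_equal(unname(s3), unname(s1) + 5, tolerance = 1e-12)
})

test_that("cadence reads the dominant spectral frequency as cycles/min", {
  w <- segment_windows(tone_signal(2), 4, 0)[[1]]
  expect_equal(cadence(w)$cycles_per_min, 120)
  w <- segment_windows(tone_signal(1.5), 4, 0)[[1]]
  expect_equal(cadence(w)$cycles_per_min, 90)
  w <- segment_windows(tone_signal(1.7), 4, 0)[[1]]
  expect_lte(abs(cadence(w)$tau - 1.7), 0.25)

  idle <- cadence(make_window(rep(1, 64)))
  expect_true(idle$idle)
  expect_equal(idle$cycles_per_min, 0)
})

test_that("recognition delay follows window_s * 0.75 + k * f(window_s)", {
  expect_equal(recognition_delay(4, 0), 3.0)
  expect_equal(recognition_delay(4, 1, identity), 7.0)
  grid <- seq(1, 20, by = 0.5)
  d <- vapply(grid, recognition_delay, numeric(1), k_device = 2,
              f_cost = function(w) w^1.5)
  expect_true(all(diff(d) >= 0))
})
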