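test_that("dF/F normalization follows both baseline conventions", {
  expect_equal(normalize_dff(c(5, 5, 5), "running_min"), c(0, 0, 0))
  expect_equal(normalize_dff(c(10, 20, 10), "global_mean"),
               c(-0.25, 0.5, -0.25))
  # monotone increasing trace: the running minimum is the first sample
  x <- cumsum(runif(50, 0.1, 1)) + 5
  expect_true(all(normalize_dff(x, "running_min") >= 0))
  expect_error(normalize_dff(c(-2, 0, 2), "global_mean"), "baseline")
  expect_error(normalize_dff(c(1, NA, 2), "running_min"), "finite")
})

make_kernel_trace <- function(pulse_times, fps = 10, duration = 60,
                              amps = 1) {
  t <- seq(0, duration - 1 / fps, by = 1 / fps)
  k <- function(u) ifelse(u < 0, 0, exp(-u / 1.5) - exp(-u / 0.1))
  amps <- rep_len(amps, length(pulse_times))
  y <- numeric(length(t))
  for (i in seq_along(pulse_times))
    y <- y + amps[i] * k(t - pulse_times[i]) / 0.7219  # unit peak
  list(t = t, y = y)
}

test_that("spike detection finds planted kernels and respects separation", {
  tr <- make_kernel_trace(10)
  sp <- detect_spikes(tr$y, tr$t)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$time_s - 10.29), 0.2)  # kernel rise-to-peak ~0.29 s

  tr2 <- make_kernel_trace(c(20, 20.5), amps = c(0.7, 1))
  sp2 <- detect_spikes(tr2$y, tr2$t, min_separation_s = 1)
  expect_identical(nrow(sp2), 1L)
  expect_gt(sp2$time_s, 20.5)  # the larger (second) kernel wins

  expect_identical(nrow(detect_spikes(rep(0, 100), seq(0, 9.9, 0.1))), 0L)
})

test_that("raising the prominence threshold never adds spikes", {
  rec <- quick_recording(seed = 8, n_trials = 8, noise_sd = 0.05)
  dff <- normalize_dff(rec$traces$values[1, ], "running_min")
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(frac)
    nrow(detect_spikes(dff, rec$traces$time_s,
                       min_prominence_frac = frac)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("events partition spikes into pulses and bursts", {
  tr <- make_kernel_trace(c(10, 12, 14), duration = 80)
  sp <- detect_spikes(tr$y, tr$t)
  ev <- segment_events(sp, tr$y, tr$t, max_gap_s = 5)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$n_pulses, 3L)
  expect_identical(ev$kind, "burst")

  tr2 <- make_kernel_trace(c(10, 40), duration = 80)
  sp2 <- detect_spikes(tr2$y, tr2$t)
  ev2 <- segment_events(sp2, tr2$y, tr2$t, max_gap_s = 5)
  expect_identical(nrow(ev2), 2L)
  expect_identical(ev2$kind, c("pulse", "pulse"))

  # partition invariant: pulse counts add up to the spike count
  rec <- quick_recording(seed = 12, n_trials = 10)
  dff <- normalize_dff(rec$traces$values[1, ], "running_min")
  sp3 <- detect_spikes(dff, rec$traces$time_s)
  ev3 <- segment_events(sp3, dff, rec$traces$time_s)
  expect_identical(sum(ev3$n_pulses), nrow(sp3))
  expect_identical(sum(ev3$kind == "pulse") + sum(ev3$kind == "burst"),
                   nrow(ev3))
})

test_that("event duration matches a brute-force threshold scan", {
  set.seed(7)
  tr <- make_kernel_trace(c(30, 32, 34, 36), duration = 120)
  y <- tr$y + rnorm(length(tr$y), 0, 0.01)
  sp <- detect_spikes(y, tr$t)
  ev <- segment_events(sp, y, tr$t, max_gap_s = 5)
  expect_identical(nrow(ev), 1L)
  # independent oracle: enumerate threshold crossings around the burst
  sigma <- mad(diff(y)) / sqrt(2)
  thr <- quantile(y[tr$t < 20], 0.10) + 3 * sigma
  above <- y >= thr
  i_peak <- which.min(abs(tr$t - sp$time_s[1]))
  start_i <- max(which(!above[1:i_peak])) + 1
  i_last <- which.min(abs(tr$t - sp$time_s[nrow(sp)]))
  end_i <- i_last + min(which(!above[i_last:length(y)])) - 1
  oracle <- tr$t[end_i] - tr$t[start_i]
  expect_lt(abs(ev$duration_s - oracle), 0.5)
})

test_that("event metrics summarize intervals and single-pulse share", {
  ev <- data.frame(start_s = c(0, 35), end_s = c(5, 40),
                   n_pulses = c(1L, 1L), kind = c("pulse", "pulse"),
                   duration_s = c(5, 5), clamped = FALSE)
  m <- event_metrics(ev)
  expect_equal(m$intervals_s, 30)

  ev2 <- data.frame(start_s = c(0, 20, 40, 60), end_s = c(2, 22, 50, 62),
                    n_pulses = c(1L, 1L, 4L, 1L),
                    kind = c("pulse", "pulse", "burst", "pulse"),
                    duration_s = c(2, 2, 10, 2), clamped = FALSE)
  expect_equal(event_metrics(ev2)$percent_single, 75)

  m1 <- event_metrics(ev2[1, , drop = FALSE])
  expect_true(m1$too_few_events)
  expect_length(m1$intervals_s, 0)
})

test_that("stimulus-locked single pulses give the cycle-locked interval", {
  # all stimulated, all single pulses: intervals are one 31 s cycle
  # minus the event width; oracle by direct enumeration of the events
  rec <- quick_recording(
    seed = 21, n_trials = 20, noise_sd = 0.01,
    response_prob_by_pressure = c("25" = 1),
    stimulated_single_pulse_fraction = 1,
    spontaneous_mean_interval_s = 0)
  an <- analyze_contractions(rec$traces, rec$protocol)
  ev <- an$events
  oracle <- median(ev$start_s[-1] - ev$end_s[-nrow(ev)])
  expect_lt(abs(an$metrics$median_interval_s - oracle), 1e-9)
  expect_lt(abs(an$metrics$median_interval_s -
                  (31 - median(ev$duration_s))), 1)
  expect_equal(an$metrics$percent_single, 100)
})
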