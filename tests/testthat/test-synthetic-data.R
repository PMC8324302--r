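test_that("stimulus protocol onsets follow the on/off cycle", {
  p <- generate_stimulus_protocol(1, 30, total_s = 3600, fps = 10)
  expect_length(p$onsets_s, 117)
  expect_equal(p$onsets_s[1:3], c(0, 31, 62))

  expect_length(generate_stimulus_protocol(1, 30, 31, fps = 10)$onsets_s, 1)

  p3 <- generate_stimulus_protocol(1, 30, total_s = 1200, pre_s = 1200,
                                   fps = 10)
  expect_length(p3$onsets_s, 39)
  expect_equal(p3$onsets_s[1], 1200)
})

test_that("invalid protocol parameters are rejected", {
  expect_error(generate_stimulus_protocol(0, 30, 100), "on_s")
  expect_error(generate_stimulus_protocol(1, -1, 100), "off_s")
  expect_error(generate_stimulus_protocol(1, 30, 0.5), "total_s")
})

test_that("spec validation enforces probability and duration invariants", {
  expect_error(synthetic_spec(burst_fraction = 1.2), "probabilities")
  expect_error(synthetic_spec(kernel_rise_s = 0), "positive")
  expect_error(synthetic_spec(duration_s = 100.05, fps = 10), "integer")
})

test_that("ground truth is deterministic in the seed", {
  proto <- generate_stimulus_protocol(1, 30, 310, pressure_psi = 25,
                                      fps = 10)
  spec <- synthetic_spec(duration_s = proto$duration_s, fps = 10, seed = 9)
  t1 <- simulate_contraction_events(spec, proto)
  t2 <- simulate_contraction_events(spec, proto)
  expect_identical(t1$pulses, t2$pulses)
  expect_identical(t1$responded_trials, t2$responded_trials)
  t3 <- simulate_contraction_events(
    synthetic_spec(duration_s = proto$duration_s, fps = 10, seed = 10),
    proto)
  expect_false(identical(t1$pulses, t3$pulses))
})

test_that("degenerate response probabilities behave as planted", {
  proto <- generate_stimulus_protocol(1, 30, 40 * 31, pressure_psi = 25,
                                      fps = 10)
  spec1 <- synthetic_spec(duration_s = proto$duration_s, fps = 10,
                          response_prob_by_pressure = c("25" = 1),
                          seed = 2)
  expect_true(all(simulate_contraction_events(spec1, proto)$responded_trials))

  spec0 <- synthetic_spec(duration_s = proto$duration_s, fps = 10,
                          response_prob_by_pressure = c("25" = 0),
                          spontaneous_mean_interval_s = 0, seed = 2)
  truth0 <- simulate_contraction_events(spec0, proto)
  expect_identical(nrow(truth0$pulses$peduncle), 0L)
  expect_false(any(truth0$responded_trials))
})

test_that("unknown pressure raises an invalid-parameter error", {
  proto <- generate_stimulus_protocol(1, 30, 62, pressure_psi = 99,
                                      fps = 10)
  spec <- synthetic_spec(duration_s = proto$duration_s, fps = 10)
  expect_error(simulate_contraction_events(spec, proto), "pressure 99")
})

test_that("responded fraction matches the planted Bernoulli rate", {
  proto <- generate_stimulus_protocol(1, 30, 119 * 31, pressure_psi = 20,
                                      fps = 10)
  fracs <- vapply(1:100, function(s) {
    spec <- synthetic_spec(duration_s = proto$duration_s, fps = 10,
                           seed = s)
    mean(simulate_contraction_events(spec, proto)$responded_trials)
  }, numeric(1))
  se <- sqrt(0.6 * 0.4 / (119 * 100))
  expect_lt(abs(mean(fracs) - 0.60), 4 * se)
})

test_that("spontaneous inter-event intervals conserve the planted mean", {
  ivals <- unlist(lapply(1:40, function(s) {
    spec <- synthetic_spec(duration_s = 3000, fps = 10, seed = s)
    p <- simulate_contraction_events(spec)$pulses$peduncle
    starts <- tapply(p$time_s, p$event_id, min)
    diff(sort(unname(starts)))
  }))
  expect_lt(abs(mean(ivals) - 73) / 73, 0.05)
})

test_that("rendered traces place kernels and baseline as specified", {
  spec <- synthetic_spec(duration_s = 60, fps = 10, noise_sd = 0,
                         spontaneous_mean_interval_s = 0, seed = 1)
  truth <- simulate_contraction_events(spec)
  # no events, no noise: exactly the bleach baseline
  tr0 <- render_calcium_traces(truth, spec)
  expect_equal(tr0$values[1, ],
               100 * 0.5^(tr0$time_s / spec$bleach_halflife_s),
               tolerance = 1e-12, ignore_attr = TRUE)
  # one planted pulse at t = 10: maximum within [10, 10 + decay]
  truth$pulses$peduncle <- data.frame(time_s = 10, event_id = 1L,
                                      kind = "pulse", stimulated = FALSE)
  tr1 <- render_calcium_traces(truth, spec)
  t_max <- tr1$time_s[which.max(tr1$values[1, ])]
  expect_gte(t_max, 10)
  expect_lte(t_max, 10 + spec$kernel_decay_s)
})

test_that("simulated tracks displace neurons only as planted", {
  proto <- generate_stimulus_protocol(1, 30, 62, pressure_psi = 22,
                                      fps = 10)
  still <- simulate_neuron_tracks(5, c(100, 100), function(r) 0, proto,
                                  jitter_sd_um = 0, seed = 1)
  d <- frame_displacements(still)
  expect_true(all(d$displacement_um == 0))

  pushed <- simulate_neuron_tracks(1, c(0, 0), function(r) 10, proto,
                                   jitter_sd_um = 0, seed = 1)
  dp <- frame_displacements(pushed)
  onset_frame <- which(diff(proto$frame_trace) == 1)[1]  # 0-based result
  expect_equal(dp$displacement_um[dp$frame == onset_frame], 10)
})

test_that("population ground truth shares pulse times within classes", {
  proto <- generate_stimulus_protocol(1, 30, 10 * 31, pressure_psi = 25,
                                      pre_s = 300, fps = 10)
  spec <- synthetic_spec(duration_s = proto$duration_s, fps = 10, seed = 4)
  truth <- simulate_population(spec, proto, n_cb = 3, n_mr = 2,
                               n_unspec = 2)
  expect_identical(truth$pulses$cb_01, truth$pulses$cb_02)
  expect_identical(truth$pulses$cb_01, truth$pulses$peduncle)
  expect_identical(truth$pulses$mr_01, truth$pulses$mr_02)
  expect_false(identical(truth$pulses$un_01, truth$pulses$un_02))
  expect_setequal(unique(truth$neuron_classes),
                  c("CB", "MR", "unspecified"))
  # MR events trail responded stimuli by roughly the planted latency
  if (nrow(truth$pulses$mr_01) > 0) {
    lat <- vapply(truth$pulses$mr_01$time_s, function(t)
      min(t - proto$onsets_s[proto$onsets_s < t]), numeric(1))
    expect_true(all(lat > 1 & lat < 20))
  }
})
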