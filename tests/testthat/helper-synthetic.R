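# Greedy one-to-one matching of detected vs planted event times.
match_events <- function(detected_s, truth_s, tol = 0.3) {
  used <- logical(length(detected_s))
  tp <- 0L
  for (t in truth_s) {
    cand <- which(!used & abs(detected_s - t) <= tol)
    if (length(cand) > 0) {
      used[cand[which.min(abs(detected_s[cand] - t))]] <- TRUE
      tp <- tp + 1L
    }
  }
  precision <- if (length(detected_s)) tp / length(detected_s) else 0
  recall <- if (length(truth_s)) tp / length(truth_s) else 0
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, precision = precision, recall = recall, f1 = f1)
}

# Time from a planted pulse to the rendered calcium peak.
peak_offset <- function(spec) {
  log(spec$kernel_decay_s / spec$kernel_rise_s) *
    spec$kernel_rise_s * spec$kernel_decay_s /
    (spec$kernel_decay_s - spec$kernel_rise_s)
}

# A short stimulated recording rendered end to end.
quick_recording <- function(seed = 1, pressure = 25, n_trials = 10,
                            pre_s = 0, fps = 10, ...) {
  proto <- generate_stimulus_protocol(1, 30, total_s = n_trials * 31,
                                      pressure_psi = pressure,
                                      pre_s = pre_s, fps = fps)
  spec <- synthetic_spec(duration_s = proto$duration_s, fps = fps,
                         seed = seed, ...)
  truth <- simulate_contraction_events(spec, proto)
  traces <- render_calcium_traces(truth, spec)
  list(protocol = proto, spec = spec, truth = truth, traces = traces)
}
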