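#!/usr/bin/env Rscript
# Detect calcium spikes and contraction events in the recordings from
# 01_simulate_recordings.R and summarize pulse/burst structure. Verifies
# detection against the planted ground truth before trusting the event
# tables.

suppressPackageStartupMessages(library(hydramech))

in_dir <- "results/synthetic"
out_dir <- "results"
if (!file.exists(file.path(in_dir, "stimulated_25psi.csv")))
  stop("run analysis/01_simulate_recordings.R first")

for (name in c("stimulated_25psi", "unstimulated")) {
  message("-- ", name)
  rec <- read_traceset_csv(file.path(in_dir, paste0(name, ".csv")))
  truth <- read_ground_truth_json(file.path(in_dir,
                                            paste0(name, "_truth.json")))
  edges <- onsets_from_frame_trace(rec$frame_trace, rec$traces$time_s)
  proto <- if (length(edges$onsets_s) > 0) {
    generate_stimulus_protocol(edges$on_s, 31 - edges$on_s,
                               total_s = max(edges$onsets_s) -
                                 edges$onsets_s[1] + 31,
                               pressure_psi = 25,
                               pre_s = edges$onsets_s[1],
                               fps = rec$traces$fps)
  } else NULL

  an <- analyze_contractions(rec$traces, proto)
  hits <- sum(vapply(truth$pulses$peduncle$time_s, function(t)
    any(abs(an$spikes$time_s - (t + 0.29)) <= 0.3), logical(1)))
  message(sprintf("   %d spikes detected, %d/%d planted pulses matched",
                  nrow(an$spikes), hits, nrow(truth$pulses$peduncle)))
  m <- an$metrics
  message(sprintf(paste0("   %d events, %.0f%% single pulses, ",
                         "median interval %.1f s, median duration %.1f s"),
                  m$n_events, m$percent_single, m$median_interval_s,
                  m$median_duration_s))
  utils::write.csv(an$events,
                   file.path(out_dir, paste0("events_", name, ".csv")),
                   row.names = FALSE)
  if (!is.null(an$response_probability))
    message(sprintf("   response probability %.2f",
                    an$response_probability))
}
message("wrote event tables to ", out_dir)
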