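#!/usr/bin/env Rscript
# Generate the synthetic recordings the downstream analyses consume:
# a stimulated peduncle-ROI recording (25 psi, standard 1 s on / 30 s off
# protocol), an unstimulated control, a tracked single-neuron population,
# and a neuron track table under valve stimulation. Traces go to CSV in
# the deposited-container layout, ground truth to JSON sidecars.

suppressPackageStartupMessages(library(hydramech))

seed <- 1L
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
fps <- 10

message("-- stimulated recording (25 psi, 40 trials + 20 min acclimation)")
proto <- generate_stimulus_protocol(1, 30, total_s = 40 * 31,
                                    pressure_psi = 25, pre_s = 1200,
                                    fps = fps)
spec <- synthetic_spec(duration_s = proto$duration_s, fps = fps,
                       seed = substream_seed(seed, 1))
truth <- simulate_contraction_events(spec, proto)
traces <- render_calcium_traces(truth, spec)
write_traceset_csv(traces, file.path(out_dir, "stimulated_25psi.csv"),
                   proto)
write_ground_truth_json(truth,
                        file.path(out_dir, "stimulated_25psi_truth.json"))
message(sprintf("   %d trials, %d planted pulses, %.0f%% trials responded",
                length(proto$onsets_s), nrow(truth$pulses$peduncle),
                100 * mean(truth$responded_trials)))

message("-- unstimulated control (40 min)")
spec0 <- synthetic_spec(duration_s = 2440, fps = fps,
                        seed = substream_seed(seed, 2))
truth0 <- simulate_contraction_events(spec0)
traces0 <- render_calcium_traces(truth0, spec0)
write_traceset_csv(traces0, file.path(out_dir, "unstimulated.csv"))
write_ground_truth_json(truth0,
                        file.path(out_dir, "unstimulated_truth.json"))
message(sprintf("   %d planted pulses over %.0f min",
                nrow(truth0$pulses$peduncle), spec0$duration_s / 60))

message("-- tracked single-neuron population (20 min spont + 10 min stim)")
nproto <- generate_stimulus_protocol(1, 30, total_s = 19 * 31,
                                     pressure_psi = 25, pre_s = 1200,
                                     fps = fps)
nspec <- synthetic_spec(duration_s = nproto$duration_s, fps = fps,
                        seed = substream_seed(seed, 3))
ntruth <- simulate_population(nspec, nproto, n_cb = 5, n_mr = 4,
                              n_unspec = 3)
ntraces <- render_calcium_traces(ntruth, nspec)
write_traceset_csv(ntraces, file.path(out_dir, "population.csv"), nproto)
write_ground_truth_json(ntruth,
                        file.path(out_dir, "population_truth.json"))
message(sprintf("   %d ROIs (%s)", length(ntruth$pulses),
                paste(names(table(ntruth$neuron_classes)),
                      table(ntruth$neuron_classes), collapse = ", ")))

message("-- neuron tracks under valve stimulation (222 neurons)")
kproto <- generate_stimulus_protocol(1, 30, total_s = 5 * 31,
                                     pressure_psi = 22, pre_s = 5,
                                     fps = fps)
profile <- function(r) ifelse(r < 200, 2, 15 * exp(-(r - 200) / 180))
tracks <- simulate_neuron_tracks(222, c(1000, 1000), profile, kproto,
                                 seed = substream_seed(seed, 4))
utils::write.csv(tracks[c("frame", "neuron_id", "x_um", "y_um")],
                 file.path(out_dir, "neuron_tracks.csv"),
                 row.names = FALSE)
message(sprintf("   %d track rows over %d frames", nrow(tracks),
                length(kproto$frame_trace)))
message("wrote ", out_dir)
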