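#' Full contraction analysis of one ROI trace
#'
#' Runs the event-detection chain on one ROI of a raw trace set:
#' running-minimum dF/F normalization, spike detection, event
#' segmentation, event metrics, and — when a protocol with onsets is
#' supplied — the stimulus-aligned raster and response probability.
#'
#' @param traces a [trace_set()].
#' @param protocol optional `stimulus_protocol`.
#' @param roi ROI label to analyze (default `"peduncle"`).
#' @param min_prominence_frac,min_separation_s see [detect_spikes()].
#' @param max_gap_s see [segment_events()].
#' @param pre_s,post_s raster window, seconds.
#' @param window_s response window, seconds.
#' @return list with `dff`, `spikes`, `events`, `metrics`, and (if
#'   stimulated) `raster` and `response_probability`.
#' @export
analyze_contractions <- function(traces, protocol = NULL,
                                 roi = "peduncle",
                                 min_prominence_frac = 0.2,
                                 min_separation_s = 1,
                                 max_gap_s = 5,
                                 pre_s = 15, post_s = 15, window_s = 1) {
  if (!roi %in% traces$roi_labels)
    stopf("ROI '%s' not in trace set", roi)
  raw <- traces$values[roi, ]
  dff <- normalize_dff(raw, method = "running_min")
  spikes <- detect_spikes(dff, traces$time_s,
                          min_prominence_frac = min_prominence_frac,
                          min_separation_s = min_separation_s)
  events <- segment_events(spikes, dff, traces$time_s,
                           max_gap_s = max_gap_s)
  out <- list(dff = dff, spikes = spikes, events = events,
              metrics = event_metrics(events))
  if (!is.null(protocol) && length(protocol$onsets_s) > 0) {
    out$raster <- build_raster(spikes, protocol, pre_s = pre_s,
                               post_s = post_s)
    out$response_probability <- response_probability(out$raster,
                                                     window_s = window_s)
  }
  out
}

#' Simulated psychometric (pressure-response) experiment
#'
#' Simulates the standard stimulus-intensity experiment — several animals
#' per valve pressure, each stimulated for `n_trials` cycles of 1 s on /
#' 30 s off — and recovers per-animal response probabilities and
#' contraction statistics through the full detection pipeline (rendered
#' fluorescence, not ground truth).
#'
#' @param pressures psi values; each must be a key of the spec's
#'   `response_prob_by_pressure` map.
#' @param n_animals animals per pressure (default 3).
#' @param n_trials stimulation cycles per animal (default 119, the
#'   standard 60 min protocol).
#' @param seed master seed; per-animal seeds are derived sub-streams.
#' @param fps rendering frame rate.
#' @param spec_args overrides passed to [synthetic_spec()].
#' @return list with `per_animal` (one row per animal x pressure,
#'   including the planted probability and the ground-truth responded
#'   fraction) and `table` (the [psychometric_table()]).
#' @export
psychometric_experiment <- function(pressures = c(5, 10, 15, 20, 25),
                                    n_animals = 3, n_trials = 119,
                                    seed = 1L, fps = 10,
                                    spec_args = list()) {
  rows <- list()
  for (p in pressures) {
    for (a in seq_len(n_animals)) {
      s <- substream_seed(seed, p * 1000L + a)
      protocol <- generate_stimulus_protocol(
        1, 30, total_s = n_trials * 31, pressure_psi = p, fps = fps)
      spec <- do.call(synthetic_spec, c(
        list(duration_s = protocol$duration_s, fps = fps, seed = s),
        spec_args))
      truth <- simulate_contraction_events(spec, protocol)
      traces <- render_calcium_traces(truth, spec, fps = fps)
      an <- analyze_contractions(traces, protocol)
      rows[[length(rows) + 1L]] <- data.frame(
        pressure_psi = p, animal = a,
        response_probability = an$response_probability,
        mean_interval_s = an$metrics$mean_interval_s,
        median_interval_s = an$metrics$median_interval_s,
        percent_single = an$metrics$percent_single,
        n_trials = length(protocol$onsets_s),
        planted_probability =
          spec$response_prob_by_pressure[[as.character(p)]],
        true_responded_fraction = mean(truth$responded_trials))
    }
  }
  per_animal <- do.call(rbind, rows)
  list(per_animal = per_animal, table = psychometric_table(per_animal))
}

#' Simulated resection-style paired experiment
#'
#' Simulates the short resection-protocol design — 20 min of no
#' stimulation followed by `n_trials` stimulation cycles per animal —
#' and compares each animal's spontaneous contraction probability
#' (sliding-window null over the unstimulated segment) with its
#' mechanosensory response probability, via a paired t test, Cohen's d
#' and Cliff's delta.
#'
#' @param n_animals number of animals (default 8).
#' @param pressure_psi valve pressure; its mapped probability is the
#'   planted response rate.
#' @param n_trials stimulation cycles (default 40, about 20 min).
#' @param pre_s unstimulated acclimation segment, seconds.
#' @param seed master seed.
#' @param fps rendering frame rate.
#' @param spec_args overrides for [synthetic_spec()].
#' @return list with `per_animal` and `comparison`
#'   (see [compare_conditions()]).
#' @export
resection_experiment <- function(n_animals = 8, pressure_psi = 20,
                                 n_trials = 40, pre_s = 1200,
                                 seed = 1L, fps = 10,
                                 spec_args = list()) {
  rows <- list()
  for (a in seq_len(n_animals)) {
    s <- substream_seed(seed, 777L + a)
    protocol <- generate_stimulus_protocol(
      1, 30, total_s = n_trials * 31, pressure_psi = pressure_psi,
      pre_s = pre_s, fps = fps)
    spec <- do.call(synthetic_spec, c(
      list(duration_s = protocol$duration_s, fps = fps, seed = s),
      spec_args))
    truth <- simulate_contraction_events(spec, protocol)
    traces <- render_calcium_traces(truth, spec, fps = fps)
    an <- analyze_contractions(traces, protocol)
    null <- spontaneous_probability_null(an$spikes, segment = c(0, pre_s))
    rows[[length(rows) + 1L]] <- data.frame(
      animal = a,
      spontaneous_probability = null$mean,
      response_probability = an$response_probability)
  }
  per_animal <- do.call(rbind, rows)
  list(per_animal = per_animal,
       comparison = compare_conditions(per_animal$spontaneous_probability,
                                       per_animal$response_probability))
}

#' Single-neuron network analysis of a multi-ROI recording
#'
#' The correlation-network chain for tracked single-neuron traces plus a
#' peduncle ROI: mean-normalized correlation matrix, block-permutation
#' z-scores, hierarchical clustering with dendrogram leaf order,
#' spontaneous-contraction- and stimulus-triggered averages, and CB / MR /
#' unspecified classification. Contraction onsets are detected from the
#' peduncle ROI over the unstimulated segment; MR latency is estimated as
#' the median latency of detected MR-ROI spikes after stimulus onsets
#' (restricted to the `lat_lo`-`lat_hi` window), which is robust to the
#' smearing of the triggered average by trial-to-trial latency jitter.
#'
#' @param traces raw [trace_set()] including a `"peduncle"` row.
#' @param protocol `stimulus_protocol` (onsets may be empty).
#' @param n_blocks,n_iter,seed see [block_shuffle_null()].
#' @param k flat cluster count for the leaf-ordered heat map
#'   (default 3: CB, MR, unspecified).
#' @param pre_s,post_s triggered-average window, seconds.
#' @param z_cb,lat_lo,lat_hi,min_peak_dff see [classify_neurons()].
#' @return list with `corr`, `null`, `clustering`, `stim_avg`,
#'   `contraction_avg`, `classification`, `mr_latency_s`.
#' @export
analyze_network <- function(traces, protocol, n_blocks = 30,
                            n_iter = 1000, seed = 1L, k = 3,
                            pre_s = 15, post_s = 15,
                            z_cb = 3, lat_lo = 5, lat_hi = 15,
                            min_peak_dff = 0.2) {
  corr <- correlation_matrix(traces, normalization = "global_mean")
  null <- block_shuffle_null(traces, n_blocks = n_blocks, n_iter = n_iter,
                             seed = seed)
  clustering <- cluster_neurons(corr, k = k)

  dff <- t(apply(traces$values, 1, normalize_dff, method = "running_min"))
  dffset <- trace_set(dff, fps = traces$fps, time_s = traces$time_s,
                      roi_labels = traces$roi_labels)

  ped <- analyze_contractions(traces, protocol = NULL, roi = "peduncle")
  spont_end <- if (length(protocol$onsets_s) > 0)
    protocol$onsets_s[1] else max(traces$time_s)
  # anchor on individual contraction pulses: burst-onset anchors would
  # put the average's maximum mid-burst (see classify_neurons)
  contraction_anchors <- ped$spikes$time_s[ped$spikes$time_s < spont_end]
  contraction_avg <- if (length(contraction_anchors) > 0) {
    tryCatch(triggered_average(dffset, contraction_anchors,
                               pre_s = pre_s, post_s = post_s),
             error = function(e) NULL)
  } else NULL

  stim_avg <- NULL
  classification <- NULL
  mr_latency <- NA_real_
  if (length(protocol$onsets_s) > 0) {
    stim_avg <- triggered_average(dffset, protocol$onsets_s,
                                  pre_s = pre_s, post_s = post_s)
    roi_spikes <- lapply(traces$roi_labels, function(roi)
      detect_spikes(dff[roi, ], traces$time_s))
    names(roi_spikes) <- traces$roi_labels
    trial_frac <- vapply(traces$roi_labels, function(roi) {
      sp <- roi_spikes[[roi]]
      if (nrow(sp) == 0) return(0)
      mean(vapply(protocol$onsets_s, function(o)
        any(sp$time_s - o >= lat_lo & sp$time_s - o <= lat_hi),
        logical(1)))
    }, numeric(1))
    classification <- classify_neurons(null$zscore, stim_avg,
                                       contraction_avg, z_cb = z_cb,
                                       lat_lo = lat_lo, lat_hi = lat_hi,
                                       min_peak_dff = min_peak_dff,
                                       mr_trial_fraction = trial_frac)
    mr_rois <- classification$roi[classification$label == "MR"]
    if (length(mr_rois) > 0) {
      lats <- unlist(lapply(mr_rois, function(roi) {
        sp <- roi_spikes[[roi]]
        if (nrow(sp) == 0) return(numeric(0))
        unlist(lapply(protocol$onsets_s, function(o) {
          l <- sp$time_s - o
          l[l >= lat_lo & l <= lat_hi]
        }))
      }))
      if (length(lats) > 0) mr_latency <- stats::median(lats)
    }
  }
  list(corr = corr, null = null, clustering = clustering,
       stim_avg = stim_avg, contraction_avg = contraction_avg,
       classification = classification, mr_latency_s = mr_latency)
}
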