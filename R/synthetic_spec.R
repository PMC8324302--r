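#' Parameters of a synthetic Hydra recording
#'
#' Bundles the statistical parameters used by the synthetic-recording
#' generator: the spontaneous contraction renewal process, the
#' pressure-dependent stimulated-response probabilities, the calcium
#' indicator kernel, and the imaging noise model.
#'
#' Defaults emulate the recordings the pipeline is designed for:
#' spontaneous contraction pulses or bursts roughly every 73 s, most
#' spontaneous events being multi-pulse bursts while stimulated events are
#' mostly single pulses, mechanically responsive (MR) neurons firing about
#' 10 s after the stimulus, and GCaMP-like kernel dynamics (fast rise, slow
#' decay).
#'
#' @param duration_s total recording length, seconds.
#' @param fps imaging rate, frames per second. `fps * duration_s` must be a
#'   whole number of frames.
#' @param spontaneous_mean_interval_s mean interval between spontaneous
#'   contraction events, seconds (default 73).
#' @param burst_fraction probability that a spontaneous event is a
#'   multi-pulse burst rather than a single pulse (default 0.83).
#' @param pulses_per_burst_mean mean pulse count of a burst; bursts have
#'   `1 + Poisson(pulses_per_burst_mean - 1)` pulses.
#' @param intra_burst_interval_s spacing between pulses within a burst,
#'   seconds.
#' @param response_prob_by_pressure named numeric vector mapping valve
#'   pressure (psi, as character names) to the probability that a stimulus
#'   evokes a contraction event.
#' @param stimulated_single_pulse_fraction probability that a stimulated
#'   event is a single pulse (default 0.60).
#' @param mr_latency_mean_s,mr_latency_sd_s latency of MR-neuron responses
#'   after stimulus onset, seconds (defaults 10 and 2).
#' @param kernel_rise_s,kernel_decay_s rise and decay time constants of the
#'   difference-of-exponentials calcium kernel, seconds.
#' @param amplitude_sdlog log-scale SD of the lognormal per-pulse amplitude
#'   (median amplitude 1 in dF/F units).
#' @param noise_sd additive Gaussian noise, dF/F units.
#' @param bleach_halflife_s photobleaching half-life of the baseline,
#'   seconds.
#' @param refractory_s spontaneous events starting within this long after a
#'   stimulated event are suppressed, seconds.
#' @param seed integer seed; all generator randomness flows from it through
#'   deterministic sub-streams.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_s = 600,
                           fps = 10,
                           spontaneous_mean_interval_s = 73,
                           burst_fraction = 0.83,
                           pulses_per_burst_mean = 6,
                           intra_burst_interval_s = 2,
                           response_prob_by_pressure = c(
                             "0" = 0, "5" = 0.09, "10" = 0.23,
                             "15" = 0.24, "20" = 0.60, "25" = 0.77),
                           stimulated_single_pulse_fraction = 0.60,
                           mr_latency_mean_s = 10,
                           mr_latency_sd_s = 2,
                           kernel_rise_s = 0.1,
                           kernel_decay_s = 1.5,
                           amplitude_sdlog = 0.25,
                           noise_sd = 0.02,
                           bleach_halflife_s = 3600,
                           refractory_s = 5,
                           seed = 1L) {
  spec <- list(
    duration_s = duration_s, fps = fps,
    spontaneous_mean_interval_s = spontaneous_mean_interval_s,
    burst_fraction = burst_fraction,
    pulses_per_burst_mean = pulses_per_burst_mean,
    intra_burst_interval_s = intra_burst_interval_s,
    response_prob_by_pressure = response_prob_by_pressure,
    stimulated_single_pulse_fraction = stimulated_single_pulse_fraction,
    mr_latency_mean_s = mr_latency_mean_s,
    mr_latency_sd_s = mr_latency_sd_s,
    kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s,
    amplitude_sdlog = amplitude_sdlog,
    noise_sd = noise_sd,
    bleach_halflife_s = bleach_halflife_s,
    refractory_s = refractory_s,
    seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  probs <- c(spec$burst_fraction, spec$stimulated_single_pulse_fraction,
             spec$response_prob_by_pressure)
  if (any(probs < 0 | probs > 1))
    stopf("all probabilities must lie in [0, 1]")
  durs <- c(spec$duration_s, spec$fps, spec$intra_burst_interval_s,
            spec$kernel_rise_s, spec$kernel_decay_s, spec$bleach_halflife_s)
  if (any(durs <= 0))
    stopf("durations, rates and time constants must be positive")
  if (spec$spontaneous_mean_interval_s < 0)
    stopf("spontaneous_mean_interval_s must be >= 0")
  n_frames <- spec$fps * spec$duration_s
  if (abs(n_frames - round(n_frames)) > 1e-8)
    stopf("fps * duration_s must be an integer frame count (got %g)",
          n_frames)
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %.0f s @ %.4g fps | spontaneous interval %.4g s,",
    x$duration_s, x$fps, x$spontaneous_mean_interval_s),
    sprintf("burst fraction %.2f | MR latency %.3g +/- %.3g s | seed %d\n",
            x$burst_fraction, x$mr_latency_mean_s, x$mr_latency_sd_s,
            x$seed))
  invisible(x)
}
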