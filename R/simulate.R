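#' Simulate contraction-circuit events for one recording
#'
#' Draws the ground-truth pulse times of the contraction circuit (the
#' signal the peduncle ROI reports). Spontaneous events follow a renewal
#' process with gamma(shape 2) inter-event intervals whose mean is
#' `spec$spontaneous_mean_interval_s`; each is a multi-pulse burst with
#' probability `spec$burst_fraction` (pulse count
#' `1 + Poisson(pulses_per_burst_mean - 1)`, pulses spaced
#' `intra_burst_interval_s` apart). At each stimulus onset an independent
#' Bernoulli draw with the pressure's response probability decides whether
#' a stimulated event occurs; its first pulse falls 0.1-0.6 s after onset
#' and it is a single pulse with probability
#' `stimulated_single_pulse_fraction`. Spontaneous events starting within
#' `refractory_s` after a stimulated event are suppressed so interval
#' statistics do not double-count a response.
#'
#' The planted response probability is the probability of a contraction
#' in the response window, the quantity the psychometric analysis
#' measures. To keep that parameter identifiable, the spontaneous process
#' is entrained the way stimulated recordings are: a stimulated event
#' resets the renewal clock (contraction rhythms lock to the stimulation
#' cycle under strong stimuli), and spontaneous pulses whose calcium peak
#' would fall inside a response window are suppressed, so every window
#' hit flows through the per-trial Bernoulli draw.
#'
#' @param spec a [synthetic_spec()].
#' @param protocol a [generate_stimulus_protocol()] result, or `NULL` for
#'   an unstimulated recording.
#' @return object of class `ground_truth`: `pulses` (named list, per ROI, of
#'   data frames with `time_s`, `event_id`, `kind`, `stimulated`),
#'   `neuron_classes`, `responded_trials`, plus the spec and protocol.
#' @export
simulate_contraction_events <- function(spec, protocol = NULL) {
  validate_synthetic_spec(spec)
  duration <- if (is.null(protocol)) spec$duration_s else protocol$duration_s

  with_seed(substream_seed(spec$seed, 1L), {
    responded <- logical(0)
    stim_events <- list()
    p <- 0
    if (!is.null(protocol) && length(protocol$onsets_s) > 0) {
      key <- as.character(protocol$pressure_psi)
      if (!key %in% names(spec$response_prob_by_pressure))
        stopf("pressure %s psi not in response_prob_by_pressure map", key)
      p <- spec$response_prob_by_pressure[[key]]
      responded <- stats::runif(length(protocol$onsets_s)) < p
      for (i in which(responded)) {
        t0 <- protocol$onsets_s[i] + stats::runif(1, 0.1, 0.6)
        single <- stats::runif(1) < spec$stimulated_single_pulse_fraction
        n_p <- if (single) 1L else 1L + stats::rpois(
          1, max(spec$pulses_per_burst_mean - 1, 0))
        stim_events[[length(stim_events) + 1L]] <-
          list(t0 = t0, n_pulses = n_p, stimulated = TRUE)
      }
    }
    stim_starts <- vapply(stim_events, `[[`, numeric(1), "t0")

    spont_events <- list()
    mean_int <- spec$spontaneous_mean_interval_s
    if (is.finite(mean_int) && mean_int > 0) {
      t <- 0
      repeat {
        cand <- t + stats::rgamma(1, shape = 2, scale = mean_int / 2)
        resets <- stim_starts[stim_starts > t & stim_starts < cand]
        if (length(resets) > 0) {
          t <- min(resets)  # stimulated event resets the renewal clock
          next
        }
        if (cand > duration) break
        single <- stats::runif(1) >= spec$burst_fraction
        n_p <- if (single) 1L else 1L + stats::rpois(
          1, max(spec$pulses_per_burst_mean - 1, 0))
        spont_events[[length(spont_events) + 1L]] <-
          list(t0 = cand, n_pulses = n_p, stimulated = FALSE)
        t <- cand
      }
    }

    keep <- vapply(spont_events, function(ev) {
      !any(ev$t0 >= stim_starts &
             ev$t0 <= stim_starts + spec$refractory_s)
    }, logical(1))
    events <- c(stim_events, spont_events[keep])

    pulses <- events_to_pulses(events, spec, duration)
    # an ineffective (0-probability) valve neither entrains nor gates
    if (!is.null(protocol) && nrow(pulses) > 0 && p > 0) {
      pulses <- suppress_window_pulses(pulses, protocol$onsets_s, spec)
    }
    truth <- list(pulses = list(peduncle = pulses),
                  neuron_classes = c(peduncle = "CB"),
                  responded_trials = responded,
                  spec = spec, protocol = protocol)
    class(truth) <- "ground_truth"
    truth
  })
}

# Drop spontaneous pulses whose calcium peak would land in (a margin
# around) a response window, then re-derive event kinds from the pulses
# that remain.
suppress_window_pulses <- function(pulses, onsets_s, spec,
                                   window = c(-0.6, 1.6)) {
  spont <- !pulses$stimulated
  if (!any(spont) || length(onsets_s) == 0) return(pulses)
  in_window <- vapply(pulses$time_s, function(t) {
    rel <- t - onsets_s
    any(rel >= window[1] & rel < window[2])
  }, logical(1))
  pulses <- pulses[!(spont & in_window), , drop = FALSE]
  if (nrow(pulses) > 0) {
    counts <- table(pulses$event_id)
    pulses$kind <- as.character(
      ifelse(as.vector(counts[as.character(pulses$event_id)]) > 1,
             "burst", "pulse"))
  }
  rownames(pulses) <- NULL
  pulses
}

events_to_pulses <- function(events, spec, duration) {
  if (length(events) == 0)
    return(data.frame(time_s = numeric(0), event_id = integer(0),
                      kind = character(0), stimulated = logical(0)))
  ord <- order(vapply(events, `[[`, numeric(1), "t0"))
  events <- events[ord]
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    times <- ev$t0 + (seq_len(ev$n_pulses) - 1) * spec$intra_burst_interval_s
    times <- times[times <= duration]
    if (length(times) == 0) return(NULL)
    data.frame(time_s = times, event_id = i,
               kind = if (length(times) > 1) "burst" else "pulse",
               stimulated = ev$stimulated)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a tracked single-neuron population
#'
#' Extends [simulate_contraction_events()] to a population of individually
#' tracked ROIs of three functional classes. Contraction-burst (CB) ROIs
#' and the peduncle ROI share the contraction-circuit pulse times.
#' Mechanically responsive (MR) ROIs fire once per responded stimulus
#' trial, all MR ROIs sharing a per-trial latency drawn from
#' `Normal(mr_latency_mean_s, mr_latency_sd_s)`. Unspecified ROIs follow
#' independent renewal processes uncoupled from both.
#'
#' @param spec a [synthetic_spec()].
#' @param protocol stimulation protocol (may be `NULL`; MR ROIs are then
#'   silent).
#' @param n_cb,n_mr,n_unspec ROI counts per class.
#' @param unspec_interval_s mean event interval of unspecified ROIs,
#'   seconds.
#' @return `ground_truth` whose `pulses` list has one entry per ROI plus a
#'   final `peduncle` entry, and `neuron_classes` naming each ROI's class.
#' @export
simulate_population <- function(spec, protocol = NULL,
                                n_cb = 5, n_mr = 4, n_unspec = 3,
                                unspec_interval_s = 90) {
  base <- simulate_contraction_events(spec, protocol)
  contraction <- base$pulses$peduncle

  mr_pulses <- data.frame(time_s = numeric(0), event_id = integer(0),
                          kind = character(0), stimulated = logical(0))
  if (!is.null(protocol) && any(base$responded_trials)) {
    mr_pulses <- with_seed(substream_seed(spec$seed, 2L), {
      onsets <- protocol$onsets_s[base$responded_trials]
      lat <- pmax(stats::rnorm(length(onsets), spec$mr_latency_mean_s,
                               spec$mr_latency_sd_s), protocol$on_s)
      times <- sort(onsets + lat)
      times <- times[times <= protocol$duration_s]
      data.frame(time_s = times, event_id = seq_along(times),
                 kind = "pulse", stimulated = TRUE)
    })
  }

  duration <- if (is.null(protocol)) spec$duration_s else protocol$duration_s
  pulses <- list()
  classes <- character(0)
  add <- function(label, df, cls) {
    pulses[[label]] <<- df
    classes[label] <<- cls
  }
  for (i in seq_len(n_cb))
    add(sprintf("cb_%02d", i), contraction, "CB")
  for (i in seq_len(n_mr))
    add(sprintf("mr_%02d", i), mr_pulses, "MR")
  for (i in seq_len(n_unspec)) {
    df <- with_seed(substream_seed(spec$seed, 10L + i), {
      ev <- list()
      t <- 0
      repeat {
        t <- t + stats::rgamma(1, shape = 2, scale = unspec_interval_s / 2)
        if (t > duration) break
        ev[[length(ev) + 1L]] <- list(t0 = t, n_pulses = 1L,
                                      stimulated = FALSE)
      }
      events_to_pulses(ev, spec, duration)
    })
    add(sprintf("un_%02d", i), df, "unspecified")
  }
  add("peduncle", contraction, "CB")

  truth <- list(pulses = pulses, neuron_classes = classes,
                responded_trials = base$responded_trials,
                spec = spec, protocol = protocol)
  class(truth) <- "ground_truth"
  truth
}

# Difference-of-exponentials calcium kernel sampled on the frame grid,
# normalized to unit peak.
calcium_kernel <- function(rise_s, decay_s, fps) {
  t_max <- decay_s * 8 + rise_s
  t <- seq(0, t_max, by = 1 / fps)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

# Time from pulse onset to the kernel's peak.
kernel_peak_offset <- function(rise_s, decay_s) {
  log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
}

#' Render raw fluorescence traces from ground truth
#'
#' Converts ground-truth pulse times into raw fluorescence: each pulse is
#' convolved with a difference-of-exponentials kernel (rise
#' `kernel_rise_s`, decay `kernel_decay_s`, unit peak) and scaled by a
#' per-pulse lognormal amplitude (median 1 dF/F); the baseline decays
#' exponentially with half-life `bleach_halflife_s` from 100 arbitrary
#' units; Gaussian noise of SD `noise_sd` (dF/F units) is added.
#'
#' @param truth a `ground_truth` from [simulate_contraction_events()] or
#'   [simulate_population()].
#' @param spec the [synthetic_spec()] (defaults to the one in `truth`).
#' @param fps frame rate of the rendered traces.
#' @return a [trace_set()] with one row per ROI.
#' @export
render_calcium_traces <- function(truth, spec = truth$spec,
                                  fps = spec$fps) {
  if (fps <= 0) stopf("fps must be positive")
  duration <- if (is.null(truth$protocol)) spec$duration_s else
    truth$protocol$duration_s
  n <- round(duration * fps)
  time_s <- (seq_len(n) - 1) / fps
  kern <- calcium_kernel(spec$kernel_rise_s, spec$kernel_decay_s, fps)
  f0 <- 100
  bleach <- f0 * 0.5^(time_s / spec$bleach_halflife_s)

  labels <- names(truth$pulses)
  values <- matrix(0, nrow = length(labels), ncol = n,
                   dimnames = list(labels, NULL))
  for (r in seq_along(labels)) {
    pt <- truth$pulses[[r]]$time_s
    values[r, ] <- with_seed(substream_seed(spec$seed, 100L + r), {
      impulses <- numeric(n)
      if (length(pt) > 0) {
        idx <- pmin(round(pt * fps) + 1L, n)
        amp <- stats::rlnorm(length(pt), 0, spec$amplitude_sdlog)
        for (j in seq_along(idx))
          impulses[idx[j]] <- impulses[idx[j]] + amp[j]
      }
      sig <- if (any(impulses != 0)) {
        stats::convolve(impulses, rev(kern), type = "open")[seq_len(n)]
      } else numeric(n)
      noise <- if (spec$noise_sd > 0)
        stats::rnorm(n, 0, spec$noise_sd) else numeric(n)
      bleach + f0 * (sig + noise)
    })
  }
  trace_set(values, fps = fps, time_s = time_s, roi_labels = labels)
}

#' Simulate neuron track tables under valve stimulation
#'
#' Places neurons uniformly over a rectangular field and generates
#' per-frame positions: on frames where the valve state changes
#' (pressurization and depressurization) every neuron is displaced radially
#' away from the valve center by `displacement_profile(r)` where `r` is its
#' distance to the valve center; all frames carry small positional jitter.
#'
#' @param n_neurons number of neurons (>= 1).
#' @param valve_center `(x, y)` valve center, micrometres.
#' @param displacement_profile function mapping distance (um) to radial
#'   displacement (um).
#' @param protocol stimulation protocol providing the frame grid and valve
#'   trace.
#' @param field_um field extent `(width, height)`, micrometres.
#' @param jitter_sd_um per-frame positional jitter SD per coordinate,
#'   micrometres. The default gives a mean frame-to-frame displacement of
#'   about 0.4 um, the baseline tissue motion these recordings show.
#' @param seed RNG seed.
#' @return data frame `(frame, time_s, neuron_id, x_um, y_um)` with
#'   attributes `valve_center` and `fps`; frames are 0-based.
#' @export
simulate_neuron_tracks <- function(n_neurons, valve_center,
                                   displacement_profile, protocol,
                                   field_um = c(2000, 2000),
                                   jitter_sd_um = 0.23,
                                   seed = 1L) {
  if (n_neurons < 1) stopf("n_neurons must be >= 1")
  n_frames <- length(protocol$frame_trace)
  with_seed(seed, {
    base_x <- stats::runif(n_neurons, 0, field_um[1])
    base_y <- stats::runif(n_neurons, 0, field_um[2])
    dx <- base_x - valve_center[1]
    dy <- base_y - valve_center[2]
    r <- sqrt(dx^2 + dy^2)
    ux <- ifelse(r > 0, dx / r, 1)
    uy <- ifelse(r > 0, dy / r, 0)
    push <- vapply(r, displacement_profile, numeric(1))

    state <- protocol$frame_trace
    transition <- c(FALSE, diff(state) != 0)
    rows <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      jx <- if (jitter_sd_um > 0)
        stats::rnorm(n_neurons, 0, jitter_sd_um) else 0
      jy <- if (jitter_sd_um > 0)
        stats::rnorm(n_neurons, 0, jitter_sd_um) else 0
      off <- if (transition[f]) push else 0
      rows[[f]] <- data.frame(
        frame = f - 1L, time_s = protocol$time_s[f],
        neuron_id = seq_len(n_neurons),
        x_um = base_x + jx + off * ux,
        y_um = base_y + jy + off * uy)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "valve_center") <- valve_center
    attr(out, "fps") <- protocol$fps
    out
  })
}

#' Render a synthetic fluorescence movie
#'
#' Builds an image stack of an elliptical body-shaped background with
#' Gaussian blobs at fixed neuron positions whose brightness follows the
#' supplied per-frame dF/F values, plus additive noise. Used to exercise
#' the image-based operations (body length, pixel cross-correlation maps).
#'
#' @param dff matrix (ROI x frame) of blob amplitudes; `NULL` for no
#'   neurons.
#' @param positions_px data frame `(x_px, y_px)`, one row per ROI.
#' @param n_frames frame count (required when `dff` is `NULL`).
#' @param frame_size `(width, height)` in pixels, each >= 64.
#' @param body_ellipse_px full `(major, minor)` axis lengths of the body
#'   ellipse, pixels; the major axis lies along x. `c(0, 0)` renders no
#'   body.
#' @param body_intensity background intensity inside the body ellipse.
#' @param blob_sigma_px Gaussian blob SD, pixels.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed for the noise.
#' @return numeric array `height x width x n_frames`.
#' @export
render_movie <- function(dff = NULL, positions_px = NULL, n_frames = NULL,
                         frame_size = c(128, 128),
                         body_ellipse_px = c(100, 40),
                         body_intensity = 0.2, blob_sigma_px = 2,
                         noise_sd = 0, seed = 1L) {
  if (any(frame_size < 64)) stopf("frame_size must be at least 64 x 64")
  if (is.null(n_frames)) {
    if (is.null(dff)) stopf("n_frames required when dff is NULL")
    n_frames <- ncol(dff)
  }
  w <- frame_size[1]; h <- frame_size[2]
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  body <- matrix(0, h, w)
  if (all(body_ellipse_px > 0)) {
    a <- body_ellipse_px[1] / 2; b <- body_ellipse_px[2] / 2
    body[((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1] <- body_intensity
  }
  blobs <- list()
  if (!is.null(dff)) {
    for (r in seq_len(nrow(dff)))
      blobs[[r]] <- exp(-(((xs - positions_px$x_px[r])^2 +
                             (ys - positions_px$y_px[r])^2) /
                            (2 * blob_sigma_px^2)))
  }
  with_seed(seed, {
    stack <- array(0, dim = c(h, w, n_frames))
    for (f in seq_len(n_frames)) {
      frame <- body
      for (r in seq_along(blobs))
        frame <- frame + dff[r, f] * blobs[[r]]
      if (noise_sd > 0)
        frame <- frame + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
      stack[, , f] <- frame
    }
    stack
  })
}
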