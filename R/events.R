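#' Baseline-normalize a fluorescence trace (dF/F)
#'
#' Two baseline conventions are used in this pipeline. `running_min`
#' divides by the running minimum of all prior timepoints,
#' `(F_t - min(F_u, u <= t)) / max(min(F_u, u <= t), eps)`; because the
#' running minimum tracks monotone photobleaching decay, no separate
#' detrending is applied. `global_mean` divides by the trace mean,
#' `(F_t - mean(F)) / mean(F)`, the convention used for single-neuron
#' correlation analysis.
#'
#' @param trace numeric vector of raw fluorescence, finite, length >= 2.
#' @param method `"running_min"` or `"global_mean"`.
#' @param eps guard against division by a near-zero baseline.
#' @return numeric vector of dF/F values.
#' @export
normalize_dff <- function(trace, method = c("running_min", "global_mean"),
                          eps = 1e-6) {
  method <- match.arg(method)
  if (length(trace) < 2) stopf("trace must have length >= 2")
  if (!all(is.finite(trace))) stopf("trace must be finite")
  if (method == "running_min") {
    f0 <- cummin(trace)
    (trace - f0) / pmax(f0, eps)
  } else {
    f0 <- mean(trace)
    if (f0 <= 0)
      stopf("degenerate baseline: non-positive trace mean under global_mean")
    (trace - f0) / f0
  }
}

# Topographic prominence of peak i: drop to the higher of the two key
# saddles, i.e. peak minus max(min left of peak until a higher sample,
# min right until a higher sample).
peak_prominence <- function(x, i) {
  h <- x[i]
  j <- i - 1L
  lo_l <- h
  while (j >= 1L && x[j] <= h) {
    if (x[j] < lo_l) lo_l <- x[j]
    j <- j - 1L
  }
  j <- i + 1L
  lo_r <- h
  n <- length(x)
  while (j <= n && x[j] <= h) {
    if (x[j] < lo_r) lo_r <- x[j]
    j <- j + 1L
  }
  h - max(lo_l, lo_r)
}

#' Detect calcium spikes in a normalized trace
#'
#' Finds local maxima whose topographic prominence exceeds a threshold,
#' then enforces a minimum pairwise separation by keeping peaks greedily
#' in decreasing amplitude order (ties broken toward earlier time).
#'
#' Before peak finding the trace is lightly smoothed (centered running
#' mean over `smooth_s`) and detrended by subtracting a rolling 10th
#' percentile baseline over `baseline_window_s`, which removes the slow
#' baseline wander the running-minimum normalization leaves when noise
#' rides on photobleaching decay. The prominence threshold is the larger
#' of `min_prominence_frac` times the trace's 95th percentile (the
#' fraction-of-largest-peak criterion used when annotating these
#' recordings) and `noise_floor_k` robust noise SDs, so that sparse-event
#' traces — where the 95th percentile sits near the noise — do not admit
#' noise peaks. The separation default is on the scale of the calcium
#' kernel width.
#'
#' @param trace normalized (dF/F) trace.
#' @param time_s per-frame timestamps, seconds.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   trace's 95th percentile (default 0.2).
#' @param min_separation_s minimum spacing between reported peaks,
#'   seconds (default 1).
#' @param smooth_s width of the pre-detection running mean, seconds.
#' @param noise_floor_k prominence floor in units of the robust noise SD
#'   (MAD of the first difference, corrected for the smoothing).
#' @param baseline_window_s rolling-percentile detrending window,
#'   seconds.
#' @return data frame `(time_s, amplitude, prominence)` sorted by time;
#'   zero rows for a flat trace.
#' @export
detect_spikes <- function(trace, time_s, min_prominence_frac = 0.2,
                          min_separation_s = 1, smooth_s = 0.5,
                          noise_floor_k = 10, baseline_window_s = 60) {
  if (min_prominence_frac <= 0 || min_separation_s <= 0)
    stopf("detection parameters must be positive")
  n <- length(trace)
  empty <- data.frame(time_s = numeric(0), amplitude = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  fps <- 1 / stats::median(diff(time_s))
  w <- max(1L, round(smooth_s * fps))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L && w < n) {
    sm <- as.numeric(stats::filter(trace, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- trace[is.na(sm)]
  } else {
    sm <- trace
    w <- 1L
  }
  x <- sm - rolling_quantile(sm, width = round(baseline_window_s * fps),
                             prob = 0.10)
  sigma_sm <- stats::mad(diff(x)) / sqrt(2) * sqrt(w)
  thr <- max(min_prominence_frac *
               stats::quantile(x, 0.95, names = FALSE),
             noise_floor_k * sigma_sm, 1e-9)
  # local maxima; ">= next" keeps the first sample of a plateau
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                 x[2:(n - 1)] >= x[3:n], FALSE)
  # prominence <= height - min(x), so this prefilter loses nothing
  cand <- which(is_peak & x >= thr + min(x))
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= thr
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0) return(empty)

  ord <- order(-x[cand], time_s[cand])
  sel <- logical(length(cand))
  sel_times <- numeric(0)
  for (k in ord) {
    t_k <- time_s[cand[k]]
    if (all(abs(sel_times - t_k) >= min_separation_s)) {
      sel[k] <- TRUE
      sel_times <- c(sel_times, t_k)
    }
  }
  # refine peak location on the unsmoothed (detrended) trace: smoothing
  # an asymmetric calcium transient shifts its maximum slightly late
  raw <- trace - rolling_quantile(trace,
                                  width = round(baseline_window_s * fps),
                                  prob = 0.10)
  half <- (w - 1L) %/% 2L
  refined <- vapply(cand[sel], function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    as.integer(lo + which.max(raw[lo:hi]) - 1L)
  }, integer(1))
  out <- data.frame(time_s = time_s[refined],
                    amplitude = x[cand[sel]],
                    prominence = prom[sel])
  out[order(out$time_s), , drop = FALSE]
}

#' Segment detected spikes into contraction events
#'
#' Groups spikes separated by at most `max_gap_s` into one contraction
#' event (a single calcium spike is a contraction pulse, a volley is a
#' contraction burst) and finds event boundaries by threshold crossing:
#' the event starts at the last upward crossing of
#' `baseline + baseline_k * sigma_noise` before the first pulse and ends
#' at the first downward crossing after the last pulse. The noise scale is
#' estimated robustly as `MAD(diff(trace)) / sqrt(2)` and the baseline as
#' a rolling 10th percentile over 60 s, both insensitive to bursts
#' occupying a large fraction of the trace. When no crossing is found
#' within `search_s`, the bound is clamped to the search window and the
#' event flagged.
#'
#' @param spikes output of [detect_spikes()].
#' @param trace,time_s the normalized trace the spikes came from.
#' @param max_gap_s spikes closer than this merge into one event
#'   (default 5, between intra-burst pulse spacing of a few seconds and
#'   inter-event intervals of tens of seconds).
#' @param baseline_k threshold height above baseline in noise SDs.
#' @param search_s how far to search for boundary crossings, seconds.
#' @return data frame `(start_s, end_s, n_pulses, kind, duration_s,
#'   clamped)`, one row per event.
#' @export
segment_events <- function(spikes, trace, time_s, max_gap_s = 5,
                           baseline_k = 3, search_s = 30) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_pulses = integer(0), kind = character(0),
                      duration_s = numeric(0), clamped = logical(0))
  if (nrow(spikes) == 0) return(empty)
  if (is.unsorted(spikes$time_s)) stopf("spikes must be sorted by time")
  fps <- 1 / stats::median(diff(time_s))
  sigma <- stats::mad(diff(trace)) / sqrt(2)
  baseline <- rolling_quantile(trace, width = round(60 * fps), prob = 0.10)
  thr <- baseline + baseline_k * max(sigma, 1e-9)
  above <- trace >= thr
  n <- length(trace)
  search_f <- round(search_s * fps)

  grp <- cumsum(c(1, diff(spikes$time_s) > max_gap_s))
  rows <- lapply(split(seq_len(nrow(spikes)), grp), function(ii) {
    t_first <- spikes$time_s[ii[1]]
    t_last <- spikes$time_s[ii[length(ii)]]
    i1 <- which.min(abs(time_s - t_first))
    i2 <- which.min(abs(time_s - t_last))
    clamped <- FALSE

    lo <- max(1L, i1 - search_f)
    below <- which(!above[lo:i1])
    if (length(below) > 0) {
      start_i <- lo + below[length(below)] - 1L + 1L  # frame after crossing
    } else {
      start_i <- lo
      clamped <- TRUE
    }
    hi <- min(n, i2 + search_f)
    below <- which(!above[i2:hi])
    if (length(below) > 0) {
      end_i <- i2 + below[1] - 1L
    } else {
      end_i <- hi
      clamped <- TRUE
    }
    start_s <- time_s[min(start_i, i1)]
    end_s <- time_s[max(end_i, i2)]
    if (end_s <= start_s) end_s <- start_s + 1 / fps
    data.frame(start_s = start_s, end_s = end_s,
               n_pulses = length(ii),
               kind = if (length(ii) > 1) "burst" else "pulse",
               duration_s = end_s - start_s, clamped = clamped)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize contraction events
#'
#' Inter-contraction intervals are measured from the end of one event to
#' the start of the next; the single-pulse percentage is the share of
#' events that are single pulses rather than bursts.
#'
#' @param events output of [segment_events()], sorted, non-overlapping.
#' @return list with `intervals_s`, `durations_s`, `percent_single`,
#'   `n_events`, and mean/median/SEM summaries; `intervals_s` is empty
#'   (flagged via `too_few_events`) for fewer than two events.
#' @export
event_metrics <- function(events) {
  n <- nrow(events)
  if (n > 1 && is.unsorted(events$start_s)) stopf("events must be sorted")
  intervals <- if (n >= 2)
    events$start_s[-1] - events$end_s[-n] else numeric(0)
  list(
    intervals_s = intervals,
    durations_s = events$duration_s,
    percent_single = if (n > 0) 100 * sum(events$kind == "pulse") / n
      else NA_real_,
    n_events = n,
    too_few_events = n < 2,
    mean_interval_s = if (length(intervals)) mean(intervals) else NA_real_,
    median_interval_s = if (length(intervals)) stats::median(intervals)
      else NA_real_,
    sem_interval_s = sem(intervals),
    mean_duration_s = if (n > 0) mean(events$duration_s) else NA_real_,
    median_duration_s = if (n > 0) stats::median(events$duration_s)
      else NA_real_)
}
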