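#' Build a valve stimulation protocol
#'
#' Constructs the on/off schedule of the microfluidic stimulation valve:
#' the valve opens for `on_s` seconds, closes for `off_s` seconds, and the
#' cycle repeats through the `total_s`-long stimulation segment, optionally
#' preceded and followed by unstimulated acclimation segments. The standard
#' protocol in this line of experiments is 1 s on / 30 s off.
#'
#' @param on_s valve-on duration, seconds (> 0).
#' @param off_s valve-off duration, seconds (>= 0).
#' @param total_s length of the stimulation segment, seconds.
#' @param pressure_psi valve pressure, psi.
#' @param pre_s unstimulated segment before stimulation starts, seconds.
#' @param post_s unstimulated segment after stimulation ends, seconds.
#' @param fps frame rate for the per-frame 0/1 valve trace.
#' @return object of class `stimulus_protocol` with fields `onsets_s`,
#'   `on_s`, `off_s`, `pressure_psi`, `pre_s`, `post_s`, `duration_s`,
#'   `fps`, `frame_trace` and `time_s`. Onsets fall at
#'   `pre_s + k * (on_s + off_s)` for every k with
#'   `onset + on_s <= pre_s + total_s`.
#' @export
generate_stimulus_protocol <- function(on_s, off_s, total_s,
                                       pressure_psi = 0,
                                       pre_s = 0, post_s = 0,
                                       fps = 10) {
  if (on_s <= 0) stopf("on_s must be positive")
  if (off_s < 0) stopf("off_s must be non-negative")
  if (total_s < on_s) stopf("total_s must be at least on_s")
  if (pre_s < 0 || post_s < 0) stopf("pre_s and post_s must be >= 0")
  if (fps <= 0) stopf("fps must be positive")

  cycle <- on_s + off_s
  n_onsets <- if (cycle > 0) floor((total_s - on_s) / cycle) + 1 else 1
  onsets <- pre_s + (seq_len(n_onsets) - 1) * cycle

  duration_s <- pre_s + total_s + post_s
  n_frames <- round(duration_s * fps)
  time_s <- (seq_len(n_frames) - 1) / fps
  frame_trace <- integer(n_frames)
  for (o in onsets) {
    # half-open [onset, onset + on_s): the onset frame is the first with 1
    idx <- which(time_s >= o - 1e-9 & time_s < o + on_s - 1e-9)
    frame_trace[idx] <- 1L
  }

  structure(list(onsets_s = onsets, on_s = on_s, off_s = off_s,
                 pressure_psi = pressure_psi, pre_s = pre_s, post_s = post_s,
                 duration_s = duration_s, fps = fps,
                 frame_trace = frame_trace, time_s = time_s),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "stimulus_protocol: %d onsets, %g s on / %g s off, %g psi, %g s total\n",
    length(x$onsets_s), x$on_s, x$off_s, x$pressure_psi, x$duration_s))
  invisible(x)
}

#' Recover stimulus onsets from a per-frame valve trace
#'
#' Deposited recordings carry the valve state as a 0/1 value per frame;
#' this reconstructs onset times from the rising edges. The onset frame is
#' the first frame with value 1 (half-open convention), and the valve-on
#' duration is the median run length of 1s times the frame period.
#'
#' @param frame_trace integer/numeric vector of 0s and 1s, one per frame.
#' @param time_s per-frame timestamps, seconds.
#' @return list with `onsets_s` (possibly empty, e.g. for unstimulated
#'   controls) and `on_s` (NA when the trace has no 1s).
#' @export
onsets_from_frame_trace <- function(frame_trace, time_s) {
  if (!all(frame_trace %in% c(0, 1)))
    stopf("frame_trace values must be 0 or 1")
  if (length(frame_trace) != length(time_s))
    stopf("frame_trace and time_s lengths differ (%d vs %d)",
          length(frame_trace), length(time_s))
  x <- as.integer(frame_trace)
  rises <- which(diff(c(0L, x)) == 1L)
  if (length(rises) == 0L)
    return(list(onsets_s = numeric(0), on_s = NA_real_))
  r <- rle(x)
  run_frames <- r$lengths[r$values == 1L]
  frame_period <- stats::median(diff(time_s))
  list(onsets_s = time_s[rises],
       on_s = stats::median(run_frames) * frame_period)
}

#' Infer the frame rate from a stimulation trace
#'
#' Recordings deposited without explicit timestamps still encode timing in
#' the valve trace: stimulation cycles repeat on a known wall-clock period
#' (31 s in the standard 1 s on / 30 s off protocol), so the median
#' inter-onset gap in frames divided by that period gives the frame rate.
#' Unstimulated traces fall back to a user-supplied rate.
#'
#' @param n_frames total frame count (used only for error messages).
#' @param frame_trace 0/1 valve state per frame.
#' @param nominal_cycle_s wall-clock stimulation cycle, seconds
#'   (default 31).
#' @param fallback_fps frame rate to return when the trace has fewer than
#'   two rising edges.
#' @return frames per second.
#' @export
infer_fps <- function(n_frames, frame_trace, nominal_cycle_s = 31,
                      fallback_fps = NULL) {
  x <- as.integer(frame_trace)
  rises <- which(diff(c(0L, x)) == 1L)
  if (length(rises) < 2) {
    if (is.null(fallback_fps))
      stopf("cannot infer fps: %d rising edge(s) and no fallback_fps",
            length(rises))
    return(fallback_fps)
  }
  stats::median(diff(rises)) / nominal_cycle_s
}
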