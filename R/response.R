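#' Build a stimulus-aligned spike raster
#'
#' Assigns each spike to every trial window it falls in (windows are
#' `[onset - pre_s, onset + post_s)` and may overlap when the stimulation
#' cycle is shorter than `pre_s + post_s`); the stored time is the spike
#' time relative to the trial's onset.
#'
#' @param spikes data frame from [detect_spikes()] (column `time_s`), or
#'   a numeric vector of spike times.
#' @param protocol a `stimulus_protocol` with non-empty onsets.
#' @param pre_s,post_s window extent around each onset, seconds
#'   (defaults 15 and 15).
#' @return object of class `spike_raster`: `trial_onsets_s`,
#'   `relative_spike_times` (list, one vector per trial), `pre_s`,
#'   `post_s`, `n_trials`.
#' @export
build_raster <- function(spikes, protocol, pre_s = 15, post_s = 15) {
  if (length(protocol$onsets_s) == 0) stopf("protocol has no onsets")
  if (pre_s < 0 || post_s < 0) stopf("pre_s and post_s must be >= 0")
  times <- if (is.data.frame(spikes)) spikes$time_s else as.numeric(spikes)
  rel <- lapply(protocol$onsets_s, function(o) {
    r <- times - o
    r[r >= -pre_s & r < post_s]
  })
  structure(list(trial_onsets_s = protocol$onsets_s,
                 relative_spike_times = rel,
                 pre_s = pre_s, post_s = post_s,
                 n_trials = length(protocol$onsets_s)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("raster: %d trials, window [-%g, %g) s, %d spikes total\n",
              x$n_trials, x$pre_s, x$post_s,
              sum(lengths(x$relative_spike_times))))
  invisible(x)
}

#' Mechanosensory response probability
#'
#' Fraction of trials with at least one spike in the response window
#' `[0, window_s)` after stimulus onset — the 1 s window during which the
#' valve is pressurized, in the standard protocol.
#'
#' @param raster a [build_raster()] result.
#' @param window_s response-window length, seconds (default 1).
#' @return fraction in `[0, 1]`.
#' @export
response_probability <- function(raster, window_s = 1) {
  if (window_s <= 0) stopf("window_s must be positive")
  if (raster$n_trials == 0)
    stopf("undefined statistic: raster has zero trials")
  hit <- vapply(raster$relative_spike_times, function(r)
    any(r >= 0 & r < window_s), logical(1))
  mean(hit)
}

#' Sliding-window spontaneous response probability
#'
#' The spontaneous null for the response probability: an unstimulated
#' segment is cut into consecutive `interval_s`-long pseudo-trials
#' (matching the stimulation cycle), and for every window offset
#' `w in {0, step_s, 2 step_s, ...}` with `w + window_s <= interval_s`
#' the fraction of pseudo-trials containing at least one spike in
#' `[w, w + window_s)` is computed. The mean over offsets is the
#' spontaneous contraction probability; the full per-offset distribution
#' is returned for rank tests against stimulated probabilities.
#'
#' @param spikes spike data frame or numeric spike times, seconds.
#' @param segment `(start, end)` of the unstimulated segment, seconds;
#'   must be at least `interval_s` long.
#' @param interval_s pseudo-trial length, seconds (default 30).
#' @param window_s window length, seconds (default 1).
#' @param step_s offset step, seconds (default 0.3).
#' @return list with `mean`, `dist` (one fraction per offset), `offsets_s`
#'   and `n_trials`.
#' @export
spontaneous_probability_null <- function(spikes, segment,
                                         interval_s = 30, window_s = 1,
                                         step_s = 0.3) {
  if (diff(segment) < interval_s)
    stopf("segment (%.1f s) shorter than interval_s (%.1f s)",
          diff(segment), interval_s)
  times <- if (is.data.frame(spikes)) spikes$time_s else as.numeric(spikes)
  times <- times[times >= segment[1] & times < segment[2]]
  n_trials <- floor(diff(segment) / interval_s)
  if (n_trials == 0) stopf("undefined statistic: zero pseudo-trials")
  rel <- (times - segment[1]) %% interval_s
  trial <- floor((times - segment[1]) / interval_s) + 1
  keep <- trial <= n_trials
  rel <- rel[keep]; trial <- trial[keep]
  offsets <- seq(0, interval_s - window_s, by = step_s)
  dist <- vapply(offsets, function(w) {
    hit_trials <- unique(trial[rel >= w & rel < w + window_s])
    length(hit_trials) / n_trials
  }, numeric(1))
  list(mean = mean(dist), dist = dist, offsets_s = offsets,
       n_trials = n_trials)
}

#' Paired comparison of spontaneous and stimulated probabilities
#'
#' Paired t test plus two effect sizes for per-animal spontaneous versus
#' stimulated response probabilities: Cohen's d on the pooled SD of the
#' two groups (n - 1 denominators; the paired version dz is also
#' reported), and Cliff's delta, the difference between the fractions of
#' cross pairs in which the stimulated value exceeds, versus falls below,
#' the spontaneous value.
#'
#' @param per_animal_spontaneous,per_animal_stimulated equal-length paired
#'   numeric vectors, one value per animal, n >= 2.
#' @return list with `t`, `df`, `p_value`, `cohens_d`, `cohens_dz`,
#'   `cliffs_delta`, `mean_spontaneous`, `mean_stimulated`, `n`,
#'   `degenerate` (TRUE when both samples have zero variance; effect
#'   sizes are then non-finite rather than an error).
#' @export
compare_conditions <- function(per_animal_spontaneous,
                               per_animal_stimulated) {
  x1 <- as.numeric(per_animal_spontaneous)
  x2 <- as.numeric(per_animal_stimulated)
  n <- length(x1)
  if (length(x2) != n) stopf("paired samples must have equal length")
  if (n < 2) stopf("paired comparison needs n >= 2")
  s1 <- stats::var(x1); s2 <- stats::var(x2)
  pooled <- sqrt(((n - 1) * s1 + (n - 1) * s2) / (2 * n - 2))
  degenerate <- pooled == 0
  d <- if (degenerate) {
    if (mean(x2) == mean(x1)) 0 else sign(mean(x2) - mean(x1)) * Inf
  } else (mean(x2) - mean(x1)) / pooled
  diffs <- x2 - x1
  dz <- if (stats::sd(diffs) == 0) {
    if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
  } else mean(diffs) / stats::sd(diffs)
  cross <- outer(x2, x1, `-`)
  delta <- (sum(cross > 0) - sum(cross < 0)) / (n * n)
  tt <- if (stats::sd(diffs) == 0) {
    list(statistic = if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf,
         parameter = n - 1,
         p.value = if (mean(diffs) == 0) 1 else 0)
  } else stats::t.test(x2, x1, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       cohens_d = d, cohens_dz = dz, cliffs_delta = delta,
       mean_spontaneous = mean(x1), mean_stimulated = mean(x2),
       n = n, degenerate = degenerate)
}

#' Psychometric summary table across stimulus pressures
#'
#' Aggregates per-animal statistics into a per-pressure table of mean and
#' SEM — per-animal values first, then across-animal summaries, matching
#' how response curves are reported for these experiments.
#'
#' @param per_animal data frame with columns `pressure_psi`, `animal`,
#'   `response_probability`, and optionally `mean_interval_s` and
#'   `percent_single`.
#' @return data frame, one row per pressure, with mean and SEM columns
#'   for each available statistic plus `n_animals`; SEM is `NA` (flagged
#'   by `n_animals == 1`) for single-animal conditions.
#' @export
psychometric_table <- function(per_animal) {
  stats_cols <- intersect(
    c("response_probability", "mean_interval_s", "percent_single"),
    names(per_animal))
  pressures <- sort(unique(per_animal$pressure_psi))
  rows <- lapply(pressures, function(p) {
    sub <- per_animal[per_animal$pressure_psi == p, , drop = FALSE]
    row <- data.frame(pressure_psi = p, n_animals = nrow(sub))
    for (cc in stats_cols) {
      row[[paste0(cc, "_mean")]] <- mean(sub[[cc]], na.rm = TRUE)
      row[[paste0(cc, "_sem")]] <- sem(sub[[cc]])
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
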