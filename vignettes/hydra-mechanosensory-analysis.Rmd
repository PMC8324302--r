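---
title: "Quantifying Hydra mechanosensory behavior from calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Hydra mechanosensory behavior from calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydramech)
```

## The problem

*Hydra vulgaris* contracts its body both spontaneously and in response to
touch. In microfluidic preparations, a push-down valve (400 µm diameter)
delivers a calibrated mechanical stimulus — 1 s of pressure every 31 s —
while calcium indicators report neural or epitheliomuscular activity.
Contractions appear in the fluorescence of the peduncle (aboral nerve
ring) region as large calcium spikes: an isolated spike is a
*contraction pulse*, a volley of spikes a *contraction burst*. The
quantitative questions this package addresses are:

* how the probability of a contraction within 1 s of a stimulus depends
  on stimulus intensity (the psychometric curve), and how that
  probability compares with a matched *spontaneous* null;
* how contraction statistics (inter-contraction interval, fraction of
  single-pulse contractions, durations) change under stimulation and
  across body resections, with paired tests and effect sizes;
* which individually tracked neurons form correlated functional groups —
  contraction-burst (CB) neurons, slow mechanically responsive (MR)
  neurons with a roughly 10 s latency, and unspecified neurons — judged
  against a block-permutation null;
* how far the valve's mechanical force extends in the tissue, from
  per-frame neuron displacements in 50 µm radial bands.

Every operation runs on real trace/track containers or on a built-in
synthetic generator that plants known ground truth, so each stage is
testable by parameter recovery.

## Event detection

Raw ROI fluorescence is normalized to ΔF/F with one of two baselines:
the *running minimum* of prior timepoints (used for event detection; it
intrinsically tracks monotone photobleaching, so no explicit detrending
is applied) or the *trace mean* (used for correlation analysis). These
mirror the two conventions used with such recordings.

`detect_spikes()` finds local maxima by topographic prominence. Two
numerical choices matter and are worth stating precisely:

* **Smoothing and detrending.** The trace is smoothed with a centred
  running mean (`smooth_s`, default 0.5 s) and detrended by a rolling
  10th-percentile baseline over 60 s before peak finding. The running
  minimum of a noisy, bleaching trace sits at an extreme noise
  excursion, which leaves a slowly wandering positive baseline in ΔF/F;
  without detrending that wander inflates the prominence of noise peaks.
  Because smoothing an asymmetric calcium transient (fast rise, slow
  decay) shifts its maximum slightly late, detected peak times are
  refined on the unsmoothed trace within the smoothing window.
* **Threshold.** The prominence threshold is
  `max(min_prominence_frac × P95, noise_floor_k × σ̂)` with
  `min_prominence_frac = 0.2` (the fraction-of-largest-peak criterion
  used when annotating such recordings, applied to the 95th percentile
  so a single outlier cannot set the scale) and a robust noise floor
  (`noise_floor_k = 10`, with `σ̂ = MAD(diff)/√2` corrected for the
  smoothing). The floor matters on sparse-event traces, where the 95th
  percentile sits near the noise and a purely relative threshold would
  admit hundreds of noise peaks; the multiplier was chosen from the
  noise-only prominence distribution so that pure-noise traces yield
  essentially no detections while the smallest realistic pulse
  amplitudes (≈ 0.5 ΔF/F) pass comfortably.

Peaks closer than `min_separation_s` (default 1 s, the kernel-width
scale) are pruned greedily by amplitude, ties toward earlier times.

`segment_events()` merges spikes separated by at most `max_gap_s` into
one contraction event. The grouping gap is genuinely unconstrained by
the source analyses; the default of 5 s sits between intra-burst pulse
spacing (a few seconds) and inter-event intervals (tens of seconds), and
is exposed for sensitivity analysis. Event boundaries are threshold
crossings of `baseline + 3σ̂` (rolling 10th-percentile baseline over
60 s; the same robust σ̂), searched up to 30 s from the first/last
pulse; events without a crossing are clamped to the search window and
flagged. Inter-contraction intervals are measured end-of-event to
start-of-next, so they are shorter than onset-to-onset spacing by one
event duration — worth remembering when comparing interval summaries
with stimulation cycle lengths.

## Response probability and the spontaneous null

Rasters align detected spike peaks to stimulus onsets with half-open
windows `[-pre, +post)`; frames are 0-based, times in seconds, and a
spike is assigned to every overlapping trial window. The response
probability is the fraction of trials with at least one spike peak in
`[0, 1 s)` — the valve-on window. The spike peak time is the membership
criterion because it is the only defined spike timestamp.

The spontaneous null replays the same measurement on unstimulated
activity: the segment is cut into 30 s pseudo-trials and a 1 s window is
slid in 0.3 s steps across the pseudo-trial, giving a distribution of
window probabilities whose mean is the spontaneous contraction
probability. Offsets are truncated so windows fit inside the interval.

Condition comparisons use a paired t test plus two effect sizes:
Cohen's *d* on the pooled SD of the two groups (the paired
standardized-difference *dz* is also reported) and Cliff's delta over
all cross pairs. Group-wise *d* is the primary version because it is
conventionally reported alongside the rank-based, group-wise Cliff's
delta; both are computed so either convention can be compared.
Per-animal statistics are aggregated first, then summarized as
mean ± SEM across animals.

## The synthetic generator

`synthetic_spec()` bundles the study conditions:

| parameter | default | meaning |
|---|---|---|
| `spontaneous_mean_interval_s` | 73 | renewal mean of spontaneous events |
| `burst_fraction` | 0.83 | spontaneous events that are bursts |
| `pulses_per_burst_mean` | 6 | mean burst size (placeholder, see below) |
| `intra_burst_interval_s` | 2 | pulse spacing in a burst (placeholder) |
| `response_prob_by_pressure` | 0.09/0.23/0.24/0.60/0.77 at 5–25 psi | planted response probability |
| `stimulated_single_pulse_fraction` | 0.60 | stimulated events that are single pulses |
| `mr_latency_mean_s`, `mr_latency_sd_s` | 10, 2 | MR response latency |
| `kernel_rise_s`, `kernel_decay_s` | 0.1, 1.5 | calcium kernel time constants |
| `noise_sd` | 0.02 | additive noise, ΔF/F units |
| `bleach_halflife_s` | 3600 | baseline photobleaching |

Spontaneous events follow a renewal process with gamma(shape 2)
inter-event intervals: only mean/median intervals are reported for such
recordings, and shape 2 avoids the unrealistic memorylessness of
exponential spacing while staying configurable. Burst size and
intra-burst spacing distributions are not reported anywhere we know of;
the defaults are placeholders chosen to look like published example
traces (volleys of several pulses a couple of seconds apart) and are
exposed in the spec. Stimulated events respond within 0.1–0.6 s of
onset (uniform), matching the observed rise of stimulated calcium
signals to peak at ~0.5–0.6 s.

Two design decisions tie the generator to the statistics it is meant to
validate:

* **The planted response probability is the total window probability.**
  The psychometric values being planted are measured quantities that
  already fold in baseline activity. If the spontaneous process were
  free to fire inside response windows, the planted parameter would not
  be what the pipeline estimates (the contamination, up to ~0.07,
  exceeds the binomial CI at low pressures). The generator therefore
  routes all response-window events through the per-trial Bernoulli
  draw: spontaneous pulses whose calcium peak would land in a response
  window are suppressed.
* **Stimulated events entrain the rhythm.** A stimulated event resets
  the renewal clock, and spontaneous events within 5 s after a
  stimulated event are suppressed (refractory rule), so interval
  statistics do not double-count responses. This mirrors the
  observation that under strong stimulation the contraction rhythm
  locks to the 31 s stimulation cycle. A valve at 0 psi (response
  probability 0) neither entrains nor gates — it is a sham stimulus.

Rendering convolves pulses with a unit-peak difference-of-exponentials
kernel (peak 0.29 s after the pulse time at the default constants),
scales by lognormal per-pulse amplitudes (median 1 ΔF/F), adds an
exponentially bleaching baseline and Gaussian noise. All randomness
flows from one seed through deterministic sub-streams
(`substream_seed()`), one per ROI/animal/replicate, so ground truth is
bit-reproducible.

What the generator does **not** emulate: motion artifacts and body
deformation, tracking errors, z-drift, indicator saturation, and —
importantly for effect sizes — animal-to-animal heterogeneity. Between
"animals" the only variance is finite-sample noise, so paired effect
sizes on synthetic cohorts come out much larger than real cohorts show
(real between-animal variance is biological). Passing recovery tests
therefore demonstrates estimator correctness, not robustness to every
artifact of real recordings.

## Single-neuron networks

Correlation matrices use mean-normalized ΔF/F over the full record.
Significance comes from a block-permutation null: each trace is cut into
30 contiguous near-equal blocks (remainder to the last block) and block
order is permuted independently per ROI, 1000 times by default (scaled
to 200 in the routine test suite), giving per-pair μ and σ and
`z = (x − μ)/σ`. Permuting independently per ROI is the stronger null
for pairwise correlation and is the interpretation implemented;
permutation is without replacement (a true block permutation preserves
each trace's sample multiset).

Clustering is agglomerative on the Euclidean distance between
correlation-matrix rows. Average linkage is the default — single
linkage, the historical default of the routine this follows, chains
badly on correlated neural data — and the method is configurable for
exact reproductions. The dendrogram leaf order sorts the heat map;
cutting at k = 3 recovers the planted CB/MR/unspecified partition.

Classification applies the functional definitions: CB requires
`z ≥ 3` against the peduncle ROI (≈ p < 0.003 two-sided under the
permutation null; no specific threshold is prescribed by the source
analyses, so it is configurable) *and* a contraction-triggered average
peaking within ±1 s of contraction onset. Contraction averages are
anchored on individual detected pulses, not burst onsets: a burst's
stacked kernels peak near its end, so onset-anchored averages of a
perfectly locked ROI peak seconds late. MR requires a
stimulus-triggered average peaking 5–15 s after onset with amplitude
≥ 0.2 ΔF/F, plus a consistency requirement (a detected spike in the
latency window in ≥ 30% of trials) that rejects ROIs whose slow
spontaneous rhythm happens to leak into a small-trial average.

The MR latency is estimated as the median latency of detected MR spikes
after stimulus onsets rather than the mode of the triggered average:
convolving the asymmetric kernel with ±2 s trial-to-trial latency
jitter shifts the average's mode about a second late, while the median
spike latency carries only the 0.29 s rise-to-peak offset.

## Kinematics

Per-frame displacements are Euclidean steps between consecutive tracked
positions (gaps are not interpolated; single-frame neurons are excluded
and reported). Baseline motion is averaged over valve-off frames;
evoked motion over the frames immediately after pressurization and
depressurization — both transitions displace tissue, outward and back —
and the two are compared with a two-sided rank-sum test. The radial
profile bins neurons by distance to the valve center *at the frame
before valve onset* (displacement would otherwise mix stimulus motion
into the binning), uses half-open 50 µm bands, and averages the top 3
displacements per band; bands with fewer than 3 neurons use all values
and are flagged, a choice the source analyses leave open.

Body length is the major axis of the moment-matched ellipse of the
largest connected component after Otsu binarization with a 2 px
closing. It is provided for artifact characterization only — body
length is an unreliable contraction readout under valve stimulation —
and feeds no response statistic.

Pixel-wise cross-correlation maps (for co-recorded electrical
reference signals) downsample frames to 64 × 64 and report the maximum
normalized cross-correlogram within ±50 ms, one trigger duty cycle,
absorbing any constant timing offset between recordings.

## I/O and orchestration

Trace sets round-trip through CSV tables (`time_s`, `stim`, `roi_*`);
ground truth through JSON sidecars; trial containers through the
deposited one-row-per-trial schema, read natively from JSON and from
MATLAB `.mat` files through a Python/scipy conversion bridge. The
deposited containers carry no timestamps, so the frame rate is inferred
from the stimulation trace against the known 31 s cycle, with an
overridable fallback for unstimulated trials. Non-finite runs of at
most 5 frames are repaired by linear interpolation; longer runs reject
the trial with a reason.

The package is organized as an analysis workflow: the numbered scripts
under `analysis/` are the orchestration layer (simulate recordings,
detect events, response statistics, networks, displacement), each a
thin narrative driver over the package functions that writes tidy
tables under `results/`. `scripts/acceptance.R` reruns the main
computations from scratch at a given seed and writes the headline
numbers as JSON.

## Problem sizes and numerical conventions

The test suite and acceptance script run the study designs at sizes the
package's authors consider statistically meaningful while staying
desk-scale: psychometric recovery with 3 animals × 119 trials per
pressure at 10 frames/s; spike-recovery over 50 seeds of 10 min traces
at noise SD 0.05; shuffle-null calibration over 100 white-noise pairs
with 200 permutations; network recovery over 20 seeds of a 30 min
(20 min spontaneous + 10 min stimulated) 13-ROI recording; displacement
profiling with 222 tracked neurons. Windows are half-open throughout;
frames are 0-based; ties in peak finding break toward earlier times;
ε-guards protect divisions by near-zero baselines, and degenerate
inputs (flat traces, empty masks, zero-variance ROIs) return flagged
values or named errors rather than NaNs.

## Known limitations

* Spike detection reports calcium peaks; it does not deconvolve
  underlying electrical spikes, which calcium imaging cannot resolve
  individually.
* The mean-normalized ΔF/F convention is not idempotent (a normalized
  trace has mean ≈ 0), so it must be applied to raw fluorescence
  exactly once; the functions do not guard against double
  normalization.
* Synthetic effect sizes overstate real ones (no animal-level
  heterogeneity, see above).
* Interval summaries use the end-to-start convention; onset-to-onset
  cycle lengths are larger by one event duration.
* The MAT reading path requires a Python with scipy on the PATH; pure-R
  environments should use the JSON container mirror.
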