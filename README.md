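# hydramech

Analysis pipeline for calcium-imaging studies of mechanosensory behavior
in *Hydra vulgaris*. In these experiments a microfluidic valve presses on
the immobilized animal (1 s on / 30 s off) while GCaMP fluorescence
reports neural or muscle activity; body contractions appear as large
calcium spikes in the peduncle region of interest. The package turns
raw ROI traces and neuron track tables into the study's quantitative
results:

* **Event detection** — ΔF/F normalization (running-minimum or
  trace-mean baseline), prominence-based spike detection, and
  segmentation into contraction *pulses* and *bursts* with
  inter-contraction intervals, durations, and the single-pulse
  percentage.
* **Response statistics** — stimulus-aligned rasters; the
  mechanosensory response probability
  `P(≥1 spike in [onset, onset+1 s))`; a spontaneous null built by
  sliding a 1 s window in 0.3 s steps across 30 s pseudo-trials of
  unstimulated activity; paired t tests with Cohen's *d*
  (pooled SD) and Cliff's delta; per-pressure psychometric tables
  (mean ± SEM across animals).
* **Functional networks** — Pearson correlation of single-neuron
  traces, significance z-scores `(x − μ)/σ` from a 30-block
  permutation null (1000 reshuffles), hierarchical clustering with
  dendrogram leaf order, spontaneous- and stimulus-triggered averages,
  and classification into contraction-burst (CB), mechanically
  responsive (MR, ~10 s latency) and unspecified neurons.
* **Kinematics** — per-frame neuron displacements, baseline vs
  valve-evoked motion with a rank-sum test, top-3 displacement
  profiles in 50 µm radial bands around the valve, and body length
  from binarized fluorescence frames.
* **Synthetic generator** — renewal-process contraction events,
  pressure-dependent stimulated responses, GCaMP-like kernels,
  bleaching and noise, neuron tracks and small movies, all with ground
  truth returned, so every stage is validated by parameter recovery.

## Worked example

Simulate a stimulated recording, run the detection chain, and compute
the response statistics:

```r
library(hydramech)

protocol <- generate_stimulus_protocol(on_s = 1, off_s = 30,
                                       total_s = 119 * 31,
                                       pressure_psi = 25, fps = 10)
spec  <- synthetic_spec(duration_s = protocol$duration_s, fps = 10,
                        seed = 42)
truth <- simulate_contraction_events(spec, protocol)
traces <- render_calcium_traces(truth, spec)
an <- analyze_contractions(traces, protocol)
an$response_probability
#> [1] 0.7478992
mean(truth$responded_trials)   # planted ground truth for this seed
#> [1] 0.7815126
an$metrics$percent_single
#> [1] 47.61905
```

The planted 25 psi response probability is 0.77; the pipeline recovers
0.748 on this seed against a realized truth of 0.782, inside the
119-trial binomial confidence band. About half the
detected contractions are single pulses, because stimulated events are
mostly single spikes while spontaneous events are mostly bursts.

The numbered scripts under `analysis/` run the full workflow and write
tidy tables under `results/`:

```sh
Rscript analysis/01_simulate_recordings.R   # synthetic recordings + truth
Rscript analysis/02_contraction_events.R    # spike/event detection
Rscript analysis/03_response_statistics.R   # psychometric + paired stats
Rscript analysis/04_neuron_networks.R       # correlation networks, CB/MR
Rscript analysis/05_tissue_displacement.R   # valve force profile
```

For example, `03_response_statistics.R` prints the recovered
psychometric curve (3 animals × 119 trials per pressure):

```
 0 psi: response probability 0.08 +/- 0.01 (planted 0.00)
 5 psi: response probability 0.08 +/- 0.01 (planted 0.09)
10 psi: response probability 0.24 +/- 0.02 (planted 0.23)
15 psi: response probability 0.22 +/- 0.02 (planted 0.24)
20 psi: response probability 0.62 +/- 0.02 (planted 0.60)
25 psi: response probability 0.71 +/- 0.01 (planted 0.77)
```

(The 0 psi row measures spontaneous contractions landing in the
response window.)

## Layout

```
R/                  package code: synthetic_spec, protocol, simulate,
                    trace_io, events, response, networks, kinematics,
                    pipeline
analysis/           numbered workflow drivers (see above)
scripts/acceptance.R
tests/testthat/     unit, property and recovery tests
vignettes/          methods vignette: models, parameters, design choices
```
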