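Package: hydramech
Title: Quantitative Analysis of Hydra Mechanosensory Calcium Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for calcium-imaging studies of mechanosensory
    behavior in Hydra vulgaris. Detects calcium spikes in region-of-interest
    fluorescence traces, annotates contraction pulses and bursts, computes
    stimulus-aligned response probabilities against a sliding-window
    spontaneous null, compares conditions with paired tests and effect sizes
    (Cohen's d, Cliff's delta), identifies correlated neuron groups via
    block-permutation correlation nulls and hierarchical clustering, and
    profiles valve-evoked tissue displacement from neuron tracks. Includes a
    synthetic-recording generator with ground truth for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
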