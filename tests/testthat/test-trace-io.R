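test_that("onsets are recovered from rising edges", {
  res <- onsets_from_frame_trace(c(0, 0, 1, 1, 0, 1, 0), 0:6)
  expect_equal(res$onsets_s, c(2, 5))
  expect_equal(res$on_s, 1.5)  # median run length of 1s (2 and 1) x 1 s

  expect_length(onsets_from_frame_trace(rep(0, 10), 0:9)$onsets_s, 0)
  expect_error(onsets_from_frame_trace(c(0, 2, 1), 0:2), "0 or 1")
})

test_that("protocol frame traces round-trip through edge detection", {
  set.seed(42)
  for (i in 1:20) {
    on_s <- sample(1:3, 1)
    off_s <- sample(5:40, 1)
    fps <- sample(c(5, 10, 16), 1)
    n <- sample(3:8, 1)
    p <- generate_stimulus_protocol(on_s, off_s,
                                    total_s = n * (on_s + off_s),
                                    pre_s = sample(0:2, 1), fps = fps)
    rec <- onsets_from_frame_trace(p$frame_trace, p$time_s)
    expect_length(rec$onsets_s, length(p$onsets_s))
    expect_true(all(abs(rec$onsets_s - p$onsets_s) <= 1 / fps + 1e-9))
  }
})

test_that("fps inference uses the nominal stimulation cycle", {
  tr <- rep(0L, 5200)
  tr[c(10, 527, 1044, 1561, 2078) + 1] <- 1L
  expect_equal(infer_fps(5200, tr, nominal_cycle_s = 31), 517 / 31)

  tr2 <- rep(0L, 100)
  tr2[c(1, 32, 63, 94)] <- 1L
  expect_equal(infer_fps(100, tr2, nominal_cycle_s = 31), 1.0)

  expect_equal(infer_fps(100, rep(0L, 100), fallback_fps = 10), 10)
  expect_error(infer_fps(100, rep(0L, 100)), "cannot infer")
})

test_that("trace_set enforces timing invariants", {
  expect_error(trace_set(matrix(1:10, 1), fps = 0), "fps")
  expect_error(trace_set(matrix(1:10, 1), fps = 1, time_s = rep(1, 10)),
               "increasing")
  expect_error(trace_set(matrix(1:10, 1), fps = 2,
                         time_s = seq(0, 9)), "inconsistent")
})

test_that("CSV trace tables round-trip exactly", {
  rec <- quick_recording(seed = 3, n_trials = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traceset_csv(rec$traces, path, rec$protocol)
  rt <- read_traceset_csv(path)
  expect_equal(rt$traces$values, rec$traces$values)
  expect_equal(rt$traces$time_s, rec$traces$time_s)
  expect_identical(rt$traces$roi_labels, rec$traces$roi_labels)
  expect_equal(rt$frame_trace, rec$protocol$frame_trace)
})

test_that("ground-truth JSON sidecars round-trip", {
  rec <- quick_recording(seed = 5, n_trials = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(rec$truth, path)
  rt <- read_ground_truth_json(path)
  expect_equal(rt$pulses$peduncle$time_s, rec$truth$pulses$peduncle$time_s)
  expect_identical(rt$pulses$peduncle$kind, rec$truth$pulses$peduncle$kind)
  expect_equal(rt$responded_trials, rec$truth$responded_trials)
})

test_that("trial containers round-trip and label conditions verbatim", {
  rec <- quick_recording(seed = 3, n_trials = 3)
  trials <- list(
    list(condition = "25", traces = rec$traces,
         frame_trace = rec$protocol$frame_trace),
    list(condition = "25", traces = rec$traces,
         frame_trace = rec$protocol$frame_trace),
    list(condition = "0", traces = rec$traces,
         frame_trace = rep(0L, length(rec$protocol$frame_trace))))
  path <- withr::local_tempfile(fileext = ".json")
  write_source_container(trials, path)
  recs <- read_source_container(path, "fig2", fallback_fps = 10)
  expect_length(recs, 3)
  expect_identical(vapply(recs, `[[`, character(1), "condition"),
                   c("25", "25", "0"))
  expect_equal(recs[[1]]$traces$values[1, ],
               rec$traces$values[1, ], ignore_attr = TRUE)
  expect_length(recs[[1]]$protocol$onsets_s, 3)
  expect_length(recs[[3]]$protocol$onsets_s, 0)  # unstimulated control
})

test_that("MATLAB containers are read through the conversion bridge", {
  rec <- quick_recording(seed = 3, n_trials = 3)
  json_tmp <- withr::local_tempfile(fileext = ".json")
  mat_tmp <- withr::local_tempfile(fileext = ".mat")
  jsonlite::write_json(
    list(fl = rec$traces$values[1, ],
         st = rec$protocol$frame_trace),
    json_tmp, digits = NA)
  script <- paste(
    "import sys, json, numpy as np",
    "from scipy.io import savemat",
    "d = json.load(open(sys.argv[1]))",
    "dt = [('StimCondition','O'),('RawFluorescenceFoot','O'),",
    "      ('StimulationTrace','O')]",
    "hd = np.zeros((2,), dtype=dt)",
    "for i in range(2):",
    "    hd[i] = ('25', np.array(d['fl']), np.array(d['st']))",
    "savemat(sys.argv[2], {'HydraData': hd})",
    sep = "\n")
  status <- system2("python", c("-c", shQuote(script), shQuote(json_tmp),
                                shQuote(mat_tmp)))
  expect_identical(status, 0L)
  recs <- read_source_container(mat_tmp, "fig2", fallback_fps = 10)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$traces$values[1, ], rec$traces$values[1, ],
               ignore_attr = TRUE)
})

test_that("schema and integrity violations are reported by name", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(HydraData = list(StimCondition = list("25"),
                          RawFluorescenceFoot = list(c(1, 2, 3)))),
    path)
  expect_error(read_source_container(path, "fig2"), "StimulationTrace")

  jsonlite::write_json(
    list(HydraData = list(StimCondition = list("25"),
                          RawFluorescenceFoot = list(c(1, 2, 3)),
                          StimulationTrace = list(c(0, 1)))),
    path)
  expect_error(read_source_container(path, "fig2"), "integrity")
})

test_that("single-neuron containers split neurons from the peduncle row", {
  path <- withr::local_tempfile(fileext = ".json")
  n_fr <- 40
  jsonlite::write_json(list(
    NeuronROI_RawFluorAllFrames = lapply(1:4, function(i)
      100 + sin(seq_len(n_fr) / i)),
    ROI_xLocAllFrames = lapply(1:3, function(i) rep(i * 10, n_fr)),
    ROI_yLocAllFrames = lapply(1:3, function(i) rep(i * 20, n_fr))),
    path, digits = NA)
  recs <- read_source_container(path, "fig4", fallback_fps = 10)
  expect_length(recs, 1)
  expect_identical(recs[[1]]$traces$roi_labels,
                   c("neuron_01", "neuron_02", "neuron_03", "peduncle"))
  expect_identical(sort(unique(recs[[1]]$tracks$neuron_id)), 1:3)
})

test_that("short non-finite runs are repaired, long runs reject the trial", {
  x <- c(1, 2, NA, NA, 5, 6)
  rep1 <- hydramech:::repair_nonfinite(x)
  expect_false(rep1$rejected)
  expect_equal(rep1$values, c(1, 2, 3, 4, 5, 6))
  rep2 <- hydramech:::repair_nonfinite(c(1, rep(NA, 6), 8))
  expect_true(rep2$rejected)
})
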