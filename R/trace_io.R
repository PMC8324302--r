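#' Multi-ROI fluorescence trace container
#'
#' @param values numeric matrix, one row per ROI, one column per frame
#'   (raw fluorescence, arbitrary units).
#' @param fps frames per second; must agree with the median spacing of
#'   `time_s` within 5 percent.
#' @param time_s per-frame timestamps, seconds, strictly increasing;
#'   defaults to a uniform grid at `fps`.
#' @param roi_labels one label per row, e.g. `"peduncle"`,
#'   `"whole_frame"`, `"neuron_03"`.
#' @return object of class `trace_set`.
#' @export
trace_set <- function(values, fps, time_s = NULL, roi_labels = NULL) {
  values <- as.matrix(values)
  if (fps <= 0) stopf("fps must be positive")
  n <- ncol(values)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / fps
  if (length(time_s) != n)
    stopf("time_s length (%d) != frame count (%d)", length(time_s), n)
  if (n > 1 && any(diff(time_s) <= 0))
    stopf("time_s must be strictly increasing")
  if (n > 1) {
    implied <- 1 / stats::median(diff(time_s))
    if (abs(implied - fps) / fps > 0.05)
      stopf("fps (%.4g) inconsistent with median frame spacing (%.4g fps)",
            fps, implied)
  }
  if (is.null(roi_labels)) roi_labels <- rownames(values)
  if (is.null(roi_labels))
    roi_labels <- sprintf("roi_%02d", seq_len(nrow(values)))
  if (length(roi_labels) != nrow(values))
    stopf("one roi label per row required")
  rownames(values) <- roi_labels
  structure(list(values = values, fps = fps, time_s = time_s,
                 roi_labels = roi_labels),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d ROI(s) x %d frames @ %.4g fps (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$fps,
              diff(range(x$time_s))))
  invisible(x)
}

#' Write / read a trace set as a CSV trace table
#'
#' Columns: `time_s`, `stim` (0/1 valve state, 0 when no protocol is
#' given), then one `roi_<label>` column per ROI. The round trip preserves
#' values, labels and timestamps.
#'
#' @param traces a [trace_set()].
#' @param path output file.
#' @param protocol optional [generate_stimulus_protocol()] supplying the
#'   `stim` column.
#' @return `write_traceset_csv`: the path, invisibly.
#' @export
write_traceset_csv <- function(traces, path, protocol = NULL) {
  stim <- if (is.null(protocol)) integer(length(traces$time_s)) else
    protocol$frame_trace[seq_along(traces$time_s)]
  df <- data.frame(time_s = traces$time_s, stim = stim)
  for (r in seq_len(nrow(traces$values)))
    df[[paste0("roi_", traces$roi_labels[r])]] <- traces$values[r, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traceset_csv
#' @return `read_traceset_csv`: a list with `traces` (a [trace_set()]) and
#'   `frame_trace` (the `stim` column).
#' @export
read_traceset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  roi_cols <- grep("^roi_", names(df), value = TRUE)
  if (length(roi_cols) == 0) stopf("no roi_* columns in %s", path)
  values <- t(as.matrix(df[roi_cols]))
  labels <- sub("^roi_", "", roi_cols)
  fps <- 1 / stats::median(diff(df$time_s))
  list(traces = trace_set(values, fps = fps, time_s = df$time_s,
                          roi_labels = labels),
       frame_trace = df$stim)
}

#' Write / read a ground-truth JSON sidecar
#'
#' @param truth a `ground_truth`.
#' @param path JSON file path.
#' @return the path (write) or the reconstructed `ground_truth` (read);
#'   the spec/protocol objects are stored as plain lists.
#' @export
write_ground_truth_json <- function(truth, path) {
  obj <- list(
    pulses = lapply(truth$pulses, function(df) as.list(df)),
    neuron_classes = as.list(truth$neuron_classes),
    responded_trials = truth$responded_trials,
    onsets_s = if (is.null(truth$protocol)) numeric(0) else
      truth$protocol$onsets_s)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$pulses <- lapply(obj$pulses, function(p)
    data.frame(time_s = as.numeric(p$time_s),
               event_id = as.integer(p$event_id),
               kind = as.character(p$kind),
               stimulated = as.logical(p$stimulated)))
  obj$neuron_classes <- unlist(obj$neuron_classes)
  class(obj) <- "ground_truth"
  obj
}

# Repair short runs of non-finite samples by linear interpolation.
# Runs longer than max_gap frames mark the trace as rejected.
repair_nonfinite <- function(x, max_gap = 5L) {
  bad <- !is.finite(x)
  if (!any(bad)) return(list(values = x, rejected = FALSE, n_repaired = 0L))
  r <- rle(bad)
  if (any(r$lengths[r$values] > max_gap) || all(bad))
    return(list(values = x, rejected = TRUE, n_repaired = sum(bad)))
  idx <- which(!bad)
  x[bad] <- stats::approx(idx, x[idx], xout = which(bad), rule = 2)$y
  list(values = x, rejected = FALSE, n_repaired = sum(bad))
}

#' Read a deposited trial container
#'
#' Reads the `HydraData` one-row-per-trial containers this line of
#' experiments deposits. Two figure schemas are supported: `"fig2"`/
#' `"fig3"` (fields `StimCondition`, `RawFluorescenceFoot`,
#' `StimulationTrace`, one peduncle or whole-frame trace per trial) and
#' `"fig4"` (per-neuron matrices `NeuronROI_RawFluorAllFrames`,
#' `ROI_xLocAllFrames`, `ROI_yLocAllFrames`; the last fluorescence row is
#' the peduncle ROI average). MATLAB `.mat` containers are converted
#' through an external Python/scipy bridge when one is available on the
#' PATH; `.json` containers with the same field names are read natively.
#'
#' Because the containers carry no timestamps, the frame rate is inferred
#' from the stimulation trace against the known 31 s stimulation cycle
#' ([infer_fps()]); unstimulated trials fall back to `fallback_fps`.
#' Non-finite fluorescence runs of at most 5 frames are repaired by linear
#' interpolation; longer runs reject the trial with a reason.
#'
#' @param path `.mat` or `.json` container.
#' @param figure_schema `"fig2"`, `"fig3"` or `"fig4"`.
#' @param fallback_fps frame rate for trials whose stimulation trace has
#'   fewer than two rising edges.
#' @param nominal_cycle_s stimulation cycle used for fps inference.
#' @return list of trial records, each with `traces` (a [trace_set()]),
#'   `protocol` (a `stimulus_protocol`, onsets possibly empty), and
#'   `condition` (the label preserved verbatim); rejected trials are
#'   returned with `rejected = TRUE` and a `reason`. For `"fig4"`,
#'   each record also carries `tracks` (a neuron track table in pixels).
#' @export
read_source_container <- function(path,
                                  figure_schema = c("fig2", "fig3", "fig4"),
                                  fallback_fps = 16.13,
                                  nominal_cycle_s = 31) {
  figure_schema <- match.arg(figure_schema)
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- if (grepl("\\.mat$", path, ignore.case = TRUE)) {
    read_mat_via_python(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (figure_schema %in% c("fig2", "fig3")) {
    parse_trial_container(obj, fallback_fps, nominal_cycle_s)
  } else {
    parse_single_neuron_container(obj, fallback_fps, nominal_cycle_s)
  }
}

read_mat_via_python <- function(path) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "")
    stopf("reading .mat requires a python with scipy on the PATH; %s",
          "convert the container to .json instead")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  script <- paste(
    "import sys, json, numpy as np",
    "from scipy.io import loadmat",
    "def clean(o):",
    "    if isinstance(o, np.ndarray):",
    "        return [clean(x) for x in o.tolist()]",
    "    if isinstance(o, (np.generic,)): return o.item()",
    "    if isinstance(o, dict):",
    "        return {k: clean(v) for k, v in o.items()",
    "                if not k.startswith('__')}",
    "    return o",
    "m = loadmat(sys.argv[1], squeeze_me=True, struct_as_record=False)",
    "def unstruct(o):",
    "    if hasattr(o, '_fieldnames'):",
    "        return {f: unstruct(getattr(o, f)) for f in o._fieldnames}",
    "    if isinstance(o, np.ndarray) and o.dtype == object:",
    "        return [unstruct(x) for x in o.tolist()]",
    "    return clean(o)",
    "out = {k: unstruct(v) for k, v in m.items()",
    "       if not k.startswith('__')}",
    "json.dump(out, open(sys.argv[2], 'w'))",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(script), shQuote(path),
                          shQuote(tmp)))
  if (status != 0) stopf("python .mat conversion failed for %s", path)
  jsonlite::read_json(tmp, simplifyVector = TRUE)
}

require_field <- function(rec, field) {
  if (is.null(rec[[field]]))
    stopf("container schema error: missing field '%s'", field)
  rec[[field]]
}

parse_trial_container <- function(obj, fallback_fps, nominal_cycle_s) {
  hd <- obj$HydraData
  if (is.null(hd)) stopf("container schema error: missing field 'HydraData'")
  # normalize: either a data-frame-like list of columns or a list of rows
  trials <- if (!is.null(names(hd)) && !is.null(hd$StimCondition)) {
    n <- length(hd$StimCondition)
    lapply(seq_len(n), function(i) lapply(hd, function(col) {
      if (is.matrix(col)) col[i, ]
      else if (is.list(col)) col[[i]]
      else col[i]
    }))
  } else hd
  lapply(trials, function(rec) {
    cond <- require_field(rec, "StimCondition")
    raw <- as.numeric(unlist(require_field(rec, "RawFluorescenceFoot")))
    stim <- as.numeric(unlist(require_field(rec, "StimulationTrace")))
    if (length(raw) != length(stim))
      stopf(paste("container integrity error: fluorescence (%d frames)",
                  "and stimulation trace (%d frames) differ"),
            length(raw), length(stim))
    rep <- repair_nonfinite(raw)
    if (rep$rejected)
      return(list(condition = cond, rejected = TRUE,
                  reason = "non-finite run longer than 5 frames"))
    fps <- infer_fps(length(raw), stim, nominal_cycle_s, fallback_fps)
    time_s <- (seq_along(raw) - 1) / fps
    edges <- onsets_from_frame_trace(stim, time_s)
    protocol <- structure(
      list(onsets_s = edges$onsets_s, on_s = edges$on_s,
           off_s = nominal_cycle_s - edges$on_s,
           pressure_psi = suppressWarnings(as.numeric(cond)),
           pre_s = if (length(edges$onsets_s)) edges$onsets_s[1] else 0,
           post_s = 0, duration_s = length(raw) / fps, fps = fps,
           frame_trace = as.integer(stim), time_s = time_s),
      class = "stimulus_protocol")
    list(condition = cond, rejected = FALSE,
         traces = trace_set(matrix(rep$values, nrow = 1), fps = fps,
                            time_s = time_s, roi_labels = "peduncle"),
         protocol = protocol, n_repaired = rep$n_repaired)
  })
}

parse_single_neuron_container <- function(obj, fallback_fps,
                                          nominal_cycle_s) {
  fl <- require_field(obj, "NeuronROI_RawFluorAllFrames")
  xs <- require_field(obj, "ROI_xLocAllFrames")
  ys <- require_field(obj, "ROI_yLocAllFrames")
  as_row_matrix <- function(m) {
    if (is.matrix(m)) m else matrix(unlist(m), nrow = length(m),
                                    byrow = TRUE)
  }
  fl <- as_row_matrix(fl)
  xs <- as_row_matrix(xs)
  ys <- as_row_matrix(ys)
  n_neurons <- nrow(fl) - 1L
  if (nrow(xs) != n_neurons || nrow(ys) != n_neurons)
    stopf(paste("container integrity error: %d fluorescence rows imply",
                "%d neurons but position matrices have %d/%d rows"),
          nrow(fl), n_neurons, nrow(xs), nrow(ys))
  stim <- obj$StimulationTrace
  fps <- if (!is.null(stim))
    infer_fps(ncol(fl), unlist(stim), nominal_cycle_s, fallback_fps)
  else fallback_fps
  time_s <- (seq_len(ncol(fl)) - 1) / fps
  labels <- c(sprintf("neuron_%02d", seq_len(n_neurons)), "peduncle")
  tracks <- data.frame(
    frame = rep(seq_len(ncol(xs)) - 1L, each = n_neurons),
    time_s = rep(time_s[seq_len(ncol(xs))], each = n_neurons),
    neuron_id = rep(seq_len(n_neurons), times = ncol(xs)),
    x_um = as.vector(xs), y_um = as.vector(ys))
  list(list(condition = "fig4", rejected = FALSE,
            traces = trace_set(fl, fps = fps, time_s = time_s,
                               roi_labels = labels),
            tracks = tracks))
}

#' Write a trial container in the deposited JSON schema
#'
#' Inverse of [read_source_container()] for the `fig2`/`fig3` schema;
#' used for round-trip tests and for exporting synthetic recordings in
#' the deposited layout.
#'
#' @param trials list of records with `condition`, `traces` (1-row
#'   [trace_set()]) and `frame_trace`.
#' @param path output `.json` path.
#' @export
write_source_container <- function(trials, path) {
  hd <- list(
    StimCondition = lapply(trials, `[[`, "condition"),
    RawFluorescenceFoot = lapply(trials, function(tr)
      as.numeric(tr$traces$values[1, ])),
    StimulationTrace = lapply(trials, function(tr)
      as.integer(tr$frame_trace)))
  jsonlite::write_json(list(HydraData = hd), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}
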