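#' Per-frame neuron displacements
#'
#' Euclidean distance between each neuron's consecutive tracked
#' positions. Missing frames produce gaps (no interpolation); neurons
#' tracked in a single frame are excluded and reported.
#'
#' @param tracks data frame `(frame, neuron_id, x_um, y_um)`; each
#'   `(neuron_id, frame)` pair at most once, coordinates finite.
#' @return data frame `(neuron_id, frame, displacement_um)` where `frame`
#'   is the later frame of each consecutive pair; attribute
#'   `excluded_neurons` lists single-frame neurons.
#' @export
frame_displacements <- function(tracks) {
  if (anyDuplicated(tracks[c("neuron_id", "frame")]))
    stopf("duplicate (neuron_id, frame) rows in track table")
  if (!all(is.finite(tracks$x_um)) || !all(is.finite(tracks$y_um)))
    stopf("track coordinates must be finite")
  excluded <- integer(0)
  rows <- lapply(split(tracks, tracks$neuron_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2) {
      excluded <<- c(excluded, tr$neuron_id[1])
      return(NULL)
    }
    consec <- diff(tr$frame) == 1
    d <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    data.frame(neuron_id = tr$neuron_id[1],
               frame = tr$frame[-1][consec],
               displacement_um = d[consec])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded_neurons") <- excluded
  out
}

#' Baseline versus valve-evoked displacement statistics
#'
#' Baseline tissue motion is the mean per-frame displacement over frames
#' when the valve is not pressurized; evoked motion is measured on the
#' frames immediately after valve pressurization and after
#' depressurization (both transitions are reported separately as well,
#' since tissue is pushed outward on pressurization and relaxes back on
#' release). A two-sided rank-sum test compares the two displacement
#' samples.
#'
#' @param displacements output of [frame_displacements()].
#' @param protocol the `stimulus_protocol` aligned to the same frames
#'   (0-based).
#' @return list with `baseline_mean_um`, `evoked_mean_um`,
#'   `evoked_on_mean_um`, `evoked_off_mean_um`, `p_value`, and sample
#'   sizes.
#' @export
stimulus_displacement_stats <- function(displacements, protocol) {
  state <- protocol$frame_trace
  n <- length(state)
  change <- diff(state)
  on_frames <- which(change == 1) + 1L - 1L   # 0-based frame after rise
  off_frames <- which(change == -1) + 1L - 1L
  if (length(on_frames) == 0)
    stopf("undefined: protocol has no valve-on frames")
  trans <- c(on_frames, off_frames)
  d <- displacements
  is_trans <- d$frame %in% trans
  is_on_state <- state[d$frame + 1L] == 1
  baseline <- d$displacement_um[!is_trans & !is_on_state]
  evoked <- d$displacement_um[is_trans]
  test <- if (length(baseline) > 0 && length(evoked) > 0)
    stats::wilcox.test(evoked, baseline)$p.value else NA_real_
  list(baseline_mean_um = mean(baseline),
       evoked_mean_um = mean(evoked),
       evoked_on_mean_um = mean(d$displacement_um[d$frame %in% on_frames]),
       evoked_off_mean_um = mean(d$displacement_um[d$frame %in% off_frames]),
       p_value = test,
       n_baseline = length(baseline), n_evoked = length(evoked))
}

#' Radial displacement profile around the valve
#'
#' Bins neurons by their distance to the valve center at the reference
#' (pre-stimulus) frame into half-open radial bands `[r, r + band_um)` and
#' reports, per band, the mean of the `top_k` largest stimulus-frame
#' displacements — a conservative profile of how far the mechanical force
#' extends, since neurons in deeper tissue layers experience less of it.
#' Bands with fewer than `top_k` neurons use all available values and are
#' flagged; empty bands are reported with `NA`.
#'
#' @param tracks track table with attribute `valve_center` (or pass
#'   `valve_center`).
#' @param stim_frame 0-based frame at which the evoked displacement is
#'   measured (typically the frame just after the first pressurization);
#'   the reference position is taken at `stim_frame - 1`.
#' @param valve_center `(x, y)` um; defaults to the track attribute.
#' @param band_um band width, micrometres (default 50).
#' @param top_k number of largest displacements averaged per band
#'   (default 3).
#' @return data frame `(band_lo_um, band_hi_um, top3_mean_um, n_neurons,
#'   partial)`.
#' @export
radial_band_profile <- function(tracks, stim_frame,
                                valve_center = attr(tracks, "valve_center"),
                                band_um = 50, top_k = 3) {
  if (is.null(valve_center)) stopf("valve_center not set")
  ref <- tracks[tracks$frame == stim_frame - 1L, , drop = FALSE]
  cur <- tracks[tracks$frame == stim_frame, , drop = FALSE]
  if (nrow(ref) == 0 || nrow(cur) == 0)
    stopf("stim_frame or its predecessor missing from track table")
  m <- merge(ref, cur, by = "neuron_id", suffixes = c("_ref", "_stim"))
  disp <- sqrt((m$x_um_stim - m$x_um_ref)^2 + (m$y_um_stim - m$y_um_ref)^2)
  r <- sqrt((m$x_um_ref - valve_center[1])^2 +
              (m$y_um_ref - valve_center[2])^2)
  band <- floor(r / band_um)
  bands <- 0:max(band)
  rows <- lapply(bands, function(b) {
    d <- sort(disp[band == b], decreasing = TRUE)
    data.frame(
      band_lo_um = b * band_um, band_hi_um = (b + 1) * band_um,
      top3_mean_um = if (length(d) == 0) NA_real_ else
        mean(utils::head(d, top_k)),
      n_neurons = length(d),
      partial = length(d) > 0 & length(d) < top_k)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Body length from a fluorescence frame
#'
#' Binarizes the frame (Otsu threshold with a small morphological
#' closing), keeps the largest connected component, and reports the major
#' axis of its moment-matched ellipse — the oral-aboral body column
#' length. Provided for artifact characterization only: body length is an
#' unreliable contraction readout under valve stimulation and is not used
#' in the response statistics.
#'
#' @param frame numeric matrix (fluorescence image).
#' @param closing_px radius of the morphological closing brush, pixels.
#' @param scale_um_per_px optional scale; lengths are returned in um
#'   when given, pixels otherwise.
#' @return length of the major axis (px or um).
#' @export
body_length <- function(frame, closing_px = 2, scale_um_per_px = NULL) {
  if (length(frame) == 0) stopf("empty image")
  rng <- range(frame)
  if (diff(rng) == 0) stopf("degenerate input: constant image")
  img <- (frame - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(img))
  mask <- img > thr
  if (!any(mask)) stopf("degenerate input: empty mask after binarization")
  brush <- EBImage::makeBrush(2 * closing_px + 1, shape = "disc")
  mask <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(labels))
  if (length(tab) == 0 || max(tab) == 0)
    stopf("degenerate input: empty mask after binarization")
  keep <- which.max(tab)
  comp <- EBImage::Image((as.integer(labels) == keep) * 1,
                         dim = dim(frame))
  feats <- EBImage::computeFeatures.moment(comp)
  len <- unname(feats[1, "m.majoraxis"])
  if (!is.null(scale_um_per_px)) len <- len * scale_um_per_px
  len
}
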