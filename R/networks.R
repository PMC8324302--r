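#' Pairwise correlation matrix of ROI traces
#'
#' Pearson correlation of mean-normalized dF/F traces over the full
#' record. Zero-variance traces get zeros in their row/column (diagonal
#' kept at 1) and are flagged rather than producing NAs.
#'
#' @param traces a [trace_set()] with at least two ROIs.
#' @param normalization `"global_mean"` (the convention for this
#'   analysis) or `"none"` if the rows are already normalized.
#' @return correlation matrix with ROI labels and attribute
#'   `flagged_rois` naming zero-variance ROIs.
#' @export
correlation_matrix <- function(traces,
                               normalization = c("global_mean", "none")) {
  normalization <- match.arg(normalization)
  m <- traces$values
  if (nrow(m) < 2) stopf("need at least 2 ROIs")
  if (normalization == "global_mean")
    m <- t(apply(m, 1, normalize_dff, method = "global_mean"))
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[flat, ] <- 0
  cc[, flat] <- 0
  diag(cc) <- 1
  dimnames(cc) <- list(traces$roi_labels, traces$roi_labels)
  attr(cc, "flagged_rois") <- traces$roi_labels[flat]
  cc
}

# Split 1..n into n_blocks contiguous near-equal blocks; the remainder
# goes to the final block.
block_index <- function(n, n_blocks) {
  base <- floor(n / n_blocks)
  sizes <- rep(base, n_blocks)
  sizes[n_blocks] <- sizes[n_blocks] + (n - base * n_blocks)
  rep(seq_len(n_blocks), times = sizes)
}

#' Block-permutation null for trace correlations
#'
#' Significance of pairwise correlations against a temporal-structure-
#' preserving null: each ROI's time series is cut into `n_blocks`
#' contiguous near-equal blocks, and in each of `n_iter` iterations the
#' block order of every ROI is independently and uniformly permuted
#' (without replacement) before recomputing the correlation matrix. The
#' per-pair mean and SD over iterations give the z-score
#' `(x - mu) / sigma` of the observed correlation.
#'
#' @param traces a [trace_set()].
#' @param n_blocks number of blocks (default 30); trace length must be at
#'   least `n_blocks`.
#' @param n_iter number of reshuffles (default 1000).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @param normalization passed to [correlation_matrix()].
#' @return list with `mu`, `sigma`, `zscore` matrices; pairs with zero
#'   null SD have `NA` z flagged in `undefined_pairs`.
#' @export
block_shuffle_null <- function(traces, n_blocks = 30, n_iter = 1000,
                               seed = 1L,
                               normalization = c("global_mean", "none")) {
  normalization <- match.arg(normalization)
  m <- traces$values
  n <- ncol(m)
  r <- nrow(m)
  if (n < n_blocks) stopf("trace length (%d) < n_blocks (%d)", n, n_blocks)
  if (normalization == "global_mean")
    m <- t(apply(m, 1, normalize_dff, method = "global_mean"))
  blk <- block_index(n, n_blocks)
  block_pos <- split(seq_len(n), blk)
  obs <- correlation_matrix(
    trace_set(m, fps = traces$fps, time_s = traces$time_s,
              roi_labels = traces$roi_labels), normalization = "none")

  with_seed(seed, {
    sum_c <- matrix(0, r, r)
    sum_c2 <- matrix(0, r, r)
    shuf <- matrix(0, r, n)
    for (it in seq_len(n_iter)) {
      for (i in seq_len(r)) {
        perm <- sample.int(n_blocks)
        shuf[i, ] <- m[i, unlist(block_pos[perm], use.names = FALSE)]
      }
      cc <- suppressWarnings(stats::cor(t(shuf)))
      cc[is.na(cc)] <- 0
      sum_c <- sum_c + cc
      sum_c2 <- sum_c2 + cc^2
    }
    mu <- sum_c / n_iter
    sigma <- sqrt(pmax(sum_c2 / n_iter - mu^2, 0) * n_iter /
                    max(n_iter - 1, 1))
    z <- (obs - mu) / sigma
    undef <- sigma == 0
    z[undef] <- NA_real_
    diag(z) <- NA_real_
    dimnames(mu) <- dimnames(sigma) <- dimnames(z) <- dimnames(obs)
    list(mu = mu, sigma = sigma, zscore = z, corr = obs,
         undefined_pairs = which(undef & upper.tri(undef), arr.ind = TRUE))
  })
}

#' Hierarchically cluster ROIs by their correlation profiles
#'
#' Agglomerative clustering on the Euclidean distance between rows of the
#' correlation matrix; the dendrogram leaf order sorts the ROIs for the
#' correlation heat map, and cutting the tree at `k` gives flat group
#' labels. Average linkage is the default — single linkage, the
#' historical default of the referenced clustering routine, chains badly
#' on correlated neural data — and the method is configurable for exact
#' reproductions.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param k optional number of flat clusters.
#' @param method linkage method passed to [stats::hclust()].
#' @return list with `leaf_order` (permutation of ROI indices),
#'   `labels` (integer cluster per ROI, `NULL` without `k`), and the
#'   `hclust` object.
#' @export
cluster_neurons <- function(corr, k = NULL, method = "average") {
  n <- nrow(corr)
  if (!is.null(k) && k > n)
    stopf("k (%d) exceeds number of ROIs (%d)", k, n)
  if (n == 1)
    return(list(leaf_order = 1L, labels = if (is.null(k)) NULL else 1L,
                hclust = NULL))
  hc <- stats::hclust(stats::dist(corr), method = method)
  labels <- if (is.null(k)) NULL else stats::cutree(hc, k = k)
  list(leaf_order = hc$order, labels = labels, hclust = hc)
}

#' Event-triggered average traces
#'
#' Averages each ROI's dF/F over windows around anchor events (stimulus
#' onsets or spontaneous contraction onsets) on a common relative time
#' grid. Anchors whose window extends outside the record are dropped and
#' counted.
#'
#' @param traces a [trace_set()] of dF/F traces (normalize first).
#' @param anchors_s anchor times, seconds, at least one.
#' @param pre_s,post_s window extent, seconds.
#' @return list with `rel_time_s`, `mean` (ROI x time matrix),
#'   `n_anchors_used`, `n_anchors_dropped`.
#' @export
triggered_average <- function(traces, anchors_s, pre_s = 15, post_s = 15) {
  if (length(anchors_s) == 0) stopf("need at least one anchor")
  fps <- traces$fps
  pre_f <- round(pre_s * fps)
  post_f <- round(post_s * fps)
  n <- ncol(traces$values)
  idx0 <- round((anchors_s - traces$time_s[1]) * fps) + 1
  ok <- idx0 - pre_f >= 1 & idx0 + post_f <= n
  if (!any(ok)) stopf("all anchors fall too close to the record edges")
  rel <- (-pre_f:post_f) / fps
  acc <- matrix(0, nrow(traces$values), length(rel))
  for (i in idx0[ok])
    acc <- acc + traces$values[, (i - pre_f):(i + post_f), drop = FALSE]
  avg <- acc / sum(ok)
  dimnames(avg) <- list(traces$roi_labels, NULL)
  list(rel_time_s = rel, mean = avg,
       n_anchors_used = sum(ok), n_anchors_dropped = sum(!ok))
}

#' Classify ROIs into CB / MR / unspecified groups
#'
#' Applies the functional definitions of the neuron groups: a
#' contraction-burst (CB) ROI has a correlation z-score against the
#' peduncle ROI of at least `z_cb` and a contraction-triggered average
#' peaking within +/-1 s of contraction onset; a mechanically responsive
#' (MR) ROI is a non-CB ROI whose stimulus-triggered average peaks
#' `lat_lo`-`lat_hi` seconds after stimulus onset (bracketing the
#' roughly 10 s MR latency) with amplitude at least `min_peak_dff`;
#' anything else is unspecified.
#'
#' @param zscore z matrix from [block_shuffle_null()], including a
#'   `"peduncle"` row/column.
#' @param stim_avg,contraction_avg [triggered_average()] results for
#'   stimulus onsets and contraction onsets (`contraction_avg` may be
#'   `NULL` when no contractions were detected).
#' @param z_cb CB z threshold (default 3, about p < 0.003 two-sided under
#'   the permutation null).
#' @param lat_lo,lat_hi MR latency window, seconds (defaults 5 and 15,
#'   bracketing the roughly 10 s MR latency).
#' @param min_peak_dff MR peak amplitude floor, dF/F units.
#' @param contraction_lock_s CB peak tolerance around contraction onset,
#'   seconds. Contraction averages should be anchored on individual
#'   contraction pulses (spike peaks), not burst onsets: a multi-pulse
#'   burst's stacked kernels peak near the end of the burst, so an
#'   onset-anchored average of a perfectly locked ROI peaks seconds late.
#' @param mr_trial_fraction named per-ROI fraction of stimulus trials
#'   with a detected spike in the latency window (optional); when given,
#'   MR additionally requires at least `min_mr_trial_fraction`, which
#'   rejects ROIs whose slow spontaneous rhythm leaks into a small-trial
#'   stimulus average at MR-like amplitude.
#' @param min_mr_trial_fraction consistency floor for MR (default 0.3).
#' @return data frame `(roi, label, z_peduncle, stim_peak_latency_s,
#'   stim_peak_dff, contraction_locked)`, one row per non-peduncle ROI.
#' @export
classify_neurons <- function(zscore, stim_avg, contraction_avg,
                             z_cb = 3, lat_lo = 5, lat_hi = 15,
                             min_peak_dff = 0.2,
                             contraction_lock_s = 1,
                             mr_trial_fraction = NULL,
                             min_mr_trial_fraction = 0.3) {
  rois <- setdiff(rownames(zscore), "peduncle")
  if (!"peduncle" %in% rownames(zscore))
    stopf("zscore must include a 'peduncle' ROI")
  rows <- lapply(rois, function(roi) {
    zp <- zscore[roi, "peduncle"]
    locked <- FALSE
    if (!is.null(contraction_avg) && roi %in% rownames(contraction_avg$mean)) {
      tr <- contraction_avg$mean[roi, ]
      pk <- contraction_avg$rel_time_s[which.max(tr)]
      locked <- abs(pk) <= contraction_lock_s
    }
    st <- stim_avg$mean[roi, ]
    pk_i <- which.max(st)
    stim_lat <- stim_avg$rel_time_s[pk_i]
    stim_amp <- st[pk_i]
    consistent <- if (is.null(mr_trial_fraction)) TRUE else
      isTRUE(mr_trial_fraction[[roi]] >= min_mr_trial_fraction)
    label <- if (!is.na(zp) && zp >= z_cb && locked) {
      "CB"
    } else if (stim_lat >= lat_lo && stim_lat <= lat_hi &&
                 stim_amp >= min_peak_dff && consistent) {
      "MR"
    } else "unspecified"
    data.frame(roi = roi, label = label, z_peduncle = unname(zp),
               stim_peak_latency_s = stim_lat, stim_peak_dff = stim_amp,
               contraction_locked = locked)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pixel-wise cross-correlation map against a reference signal
#'
#' Downsamples each movie frame to a coarse grid (64 x 64 by default) and
#' cross-correlates each downsampled pixel's time course with a reference
#' signal, reporting the maximum of the normalized cross-correlogram over
#' lags of at most `max_lag_s` (about one duty cycle of the acquisition
#' trigger, absorbing any constant timing offset between the two
#' recordings).
#'
#' @param movie array `height x width x frames`.
#' @param reference numeric vector, same frame count as the movie.
#' @param fps frame rate, frames/second.
#' @param grid downsampled size (single integer, default 64).
#' @param max_lag_s maximum absolute lag, seconds (default 0.05); a delay
#'   of exactly `max_lag_s` is still inside the window.
#' @return `grid x grid` matrix of maximal correlations; constant pixels
#'   map to 0 and are flagged in attribute `flagged_pixels`.
#' @export
pixel_crosscorrelation_map <- function(movie, reference, fps,
                                       grid = 64, max_lag_s = 0.05) {
  dims <- dim(movie)
  if (length(dims) != 3) stopf("movie must be a 3-d array")
  if (dims[3] != length(reference))
    stopf("movie (%d frames) and reference (%d) lengths differ",
          dims[3], length(reference))
  small <- array(0, dim = c(grid, grid, dims[3]))
  for (f in seq_len(dims[3]))
    small[, , f] <- EBImage::resize(movie[, , f], w = grid, h = grid)
  max_lag <- floor(max_lag_s * fps + 1e-9)
  lags <- -max_lag:max_lag
  n <- dims[3]
  out <- matrix(0, grid, grid)
  flagged <- matrix(FALSE, grid, grid)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      px <- small[i, j, ]
      if (stats::sd(px) == 0) {
        flagged[i, j] <- TRUE
        next
      }
      best <- -Inf
      for (lag in lags) {
        if (lag >= 0) {
          a <- px[(1 + lag):n]; b <- reference[1:(n - lag)]
        } else {
          a <- px[1:(n + lag)]; b <- reference[(1 - lag):n]
        }
        if (stats::sd(a) == 0 || stats::sd(b) == 0) next
        best <- max(best, stats::cor(a, b))
      }
      out[i, j] <- if (is.finite(best)) best else 0
    }
  }
  attr(out, "flagged_pixels") <- which(flagged, arr.ind = TRUE)
  out
}
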