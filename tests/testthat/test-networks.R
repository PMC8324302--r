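test_that("correlation matrix handles perfect and degenerate cases", {
  x <- sin(seq(0, 20, 0.1)) + 2
  tr <- trace_set(rbind(x, x, 4 - x, rep(3, length(x))), fps = 10,
                  roi_labels = c("a", "b", "neg", "flat"))
  cc <- correlation_matrix(tr)
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "neg"], -1)
  expect_equal(cc["a", "flat"], 0)
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_identical(attr(cc, "flagged_rois"), "flat")
  expect_true(isSymmetric(unname(cc)))
  expect_error(correlation_matrix(trace_set(matrix(1:5, 1), fps = 1)),
               "2 ROIs")
})

test_that("planted CB pairs correlate, CB and MR do not", {
  ok_within <- c(); ok_across <- c()
  for (s in 1:5) {
    proto <- generate_stimulus_protocol(1, 30, 10 * 31, pressure_psi = 25,
                                        pre_s = 300, fps = 10)
    spec <- synthetic_spec(duration_s = proto$duration_s, fps = 10,
                           seed = s)
    truth <- simulate_population(spec, proto, n_cb = 2, n_mr = 1,
                                 n_unspec = 0)
    cc <- correlation_matrix(render_calcium_traces(truth, spec))
    ok_within <- c(ok_within, cc["cb_01", "cb_02"])
    ok_across <- c(ok_across, cc["cb_01", "mr_01"])
  }
  expect_true(all(ok_within > 0.8))
  expect_true(all(abs(ok_across) < 0.2))
})

test_that("block partition covers the series with the remainder last", {
  idx <- hydramech:::block_index(305, 30)
  expect_length(idx, 305)
  sizes <- as.integer(table(idx))
  expect_identical(sizes[1:29], rep(10L, 29))
  expect_identical(sizes[30], 15L)
})

test_that("block-shuffle z-scores are reproducible and calibrated", {
  set.seed(2)
  m <- matrix(rnorm(2 * 1500), nrow = 2) + 10
  tr <- trace_set(m, fps = 10)
  n1 <- block_shuffle_null(tr, n_blocks = 30, n_iter = 100, seed = 7)
  n2 <- block_shuffle_null(tr, n_blocks = 30, n_iter = 100, seed = 7)
  expect_identical(n1$zscore, n2$zscore)       # bit-identical under a seed
  expect_true(is.na(n1$zscore[1, 1]))

  zs <- vapply(1:25, function(i) {
    m <- matrix(rnorm(2 * 1200), nrow = 2) + 10
    block_shuffle_null(trace_set(m, fps = 10), n_blocks = 30,
                       n_iter = 100, seed = i)$zscore[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.5)   # ~N(0, 1/25) for independent noise
  expect_lt(sd(zs), 1.5)

  # identical ROIs: strongly significant correlation
  x <- abs(rnorm(1500)) + 10
  ni <- block_shuffle_null(trace_set(rbind(x, x), fps = 10),
                           n_blocks = 30, n_iter = 100, seed = 1)
  expect_gte(ni$zscore[1, 2], 5)

  expect_error(block_shuffle_null(trace_set(matrix(1:40, 2), fps = 1),
                                  n_blocks = 30), "n_blocks")
})

test_that("clustering keeps planted blocks contiguous and separable", {
  blockm <- matrix(0, 6, 6)
  blockm[1:3, 1:3] <- 1
  blockm[4:6, 4:6] <- 1
  diag(blockm) <- 1
  cl <- cluster_neurons(blockm, k = 2)
  groups <- cl$labels[cl$leaf_order]
  expect_identical(length(rle(groups)$lengths), 2L)  # contiguous blocks
  expect_identical(unname(cl$labels[1:3]), rep(cl$labels[[1]], 3))
  expect_false(cl$labels[1] == cl$labels[4])

  expect_identical(cluster_neurons(matrix(1, 1, 1))$leaf_order, 1L)
  expect_error(cluster_neurons(blockm, k = 7), "exceeds")
})

test_that("triggered averages align planted responses and shrink noise", {
  x <- c(rep(0, 50), 1:10, rep(0, 140))
  tr <- trace_set(matrix(x, 1), fps = 10, roi_labels = "a")
  avg <- triggered_average(tr, anchors_s = 5, pre_s = 2, post_s = 2)
  expect_equal(avg$mean[1, ], x[31:71], ignore_attr = TRUE)
  expect_identical(avg$n_anchors_used, 1L)

  # amplitude of a pure-noise average shrinks like 1/sqrt(n)
  set.seed(4)
  noise <- trace_set(matrix(rnorm(20000), 1), fps = 10, roi_labels = "a")
  sds <- vapply(c(1, 4, 16), function(n) {
    a <- triggered_average(noise, anchors_s = seq(100, by = 100,
                                                  length.out = n),
                           pre_s = 15, post_s = 15)
    sd(a$mean[1, ])
  }, numeric(1))
  expect_lt(abs(sds[2] / sds[1] - 0.5), 0.25)
  expect_lt(abs(sds[3] / sds[2] - 0.5), 0.25)

  expect_error(triggered_average(noise, anchors_s = 1, pre_s = 50,
                                 post_s = 50), "edges")
})

test_that("planted classes are labeled CB, MR and unspecified", {
  proto <- generate_stimulus_protocol(1, 30, 19 * 31, pressure_psi = 25,
                                      pre_s = 1200, fps = 10)
  for (s in 1:3) {
    spec <- synthetic_spec(duration_s = proto$duration_s, fps = 10,
                           seed = s)
    truth <- simulate_population(spec, proto, n_cb = 3, n_mr = 2,
                                 n_unspec = 2)
    net <- analyze_network(render_calcium_traces(truth, spec), proto,
                           n_iter = 100, seed = s)
    cls <- net$classification
    truecl <- truth$neuron_classes[cls$roi]
    expect_gte(mean(cls$label == truecl), 6 / 7)
    expect_true(all(cls$label[truecl == "CB"] == "CB"))
  }
})

test_that("cross-correlation maps localize a responsive blob", {
  set.seed(6)
  ref <- rnorm(80)
  mov <- render_movie(dff = matrix(ref, 1),
                      positions_px = data.frame(x_px = 90, y_px = 40),
                      frame_size = c(128, 128), body_ellipse_px = c(0, 0),
                      noise_sd = 0.05, seed = 2)
  m <- pixel_crosscorrelation_map(mov, ref, fps = 20, grid = 64,
                                  max_lag_s = 0.05)
  pk <- which(m == max(m), arr.ind = TRUE)
  # blob at image (row 40, col 90) maps to grid cell (20, 45)
  expect_lt(abs(pk[1, 1] - 20), 2)
  expect_lt(abs(pk[1, 2] - 45), 2)

  # a pixel trace equal to the reference, and one delayed by exactly the
  # window bound, both reach correlation 1
  mov2 <- array(rep(ref, each = 64 * 64), dim = c(64, 64, 80))
  expect_equal(max(pixel_crosscorrelation_map(mov2, ref, fps = 20)), 1)
  ref_delayed <- c(0, ref[-80])
  m3 <- pixel_crosscorrelation_map(mov2[, , ], ref_delayed, fps = 20,
                                   max_lag_s = 0.05)
  expect_equal(max(m3), 1)

  const <- array(1, dim = c(64, 64, 80))
  mc <- pixel_crosscorrelation_map(const, ref, fps = 20)
  expect_true(all(mc == 0))
  expect_gt(nrow(attr(mc, "flagged_pixels")), 0)
})
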