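# Background subtraction, correlation-seeded segmentation, trace
# extraction, dF/F.

make_blob_movie <- function(n_frames = 120, h = 30, w = 30, centers,
                            signals, sigma = 1.5, amp = 100, bg = 50,
                            noise_sd = 0, seed = 1) {
  set.seed(seed)
  arr <- array(bg, dim = c(n_frames, h, w))
  for (j in seq_along(signals)) {
    cr <- centers[j, 1]; cc <- centers[j, 2]
    for (r in max(1, cr - 5):min(h, cr + 5))
      for (ci in max(1, cc - 5):min(w, cc + 5)) {
        g <- exp(-((r - cr)^2 + (ci - cc)^2) / (2 * sigma^2))
        arr[, r, ci] <- arr[, r, ci] + amp * g * signals[[j]]
      }
  }
  if (noise_sd > 0) arr <- arr + rnorm(length(arr), sd = noise_sd)
  nm_movie(arr, seq_len(n_frames) / 20)
}

test_that("background subtraction removes a per-frame scalar and clips at 0", {
  mov <- nm_movie(array(100, dim = c(20, 8, 8)), seq_len(20) / 20)
  out <- subtract_background(mov, percentile = 5)
  expect_true(all(out$pixels == 0))

  set.seed(1)
  noisy <- nm_movie(array(rnorm(20 * 64, 10, 5), dim = c(20, 8, 8)),
                    seq_len(20) / 20)
  expect_true(all(subtract_background(noisy)$pixels >= 0))
  expect_error(subtract_background(mov, percentile = 60), "percentile")
})

test_that("background subtraction preserves blob amplitude over background", {
  sig <- list(1 + sin(seq_len(120) / 5))
  mov <- make_blob_movie(centers = cbind(15, 15), signals = sig)
  out <- subtract_background(mov, percentile = 5)
  # blob-centre pixel should carry amp * signal after removing bg = 50
  expect_equal(out$pixels[, 15, 15], 100 * sig[[1]], tolerance = 1e-9)
})

test_that("segmentation finds nothing in iid noise", {
  set.seed(3)
  mov <- nm_movie(array(rnorm(60 * 400), dim = c(60, 20, 20)),
                  seq_len(60) / 20)
  rois <- segment_rois(mov, seed_quantile = 0.95, grow_threshold = 0.5)
  expect_length(rois, 0)
})

test_that("segmentation recovers three disjoint blobs with Jaccard >= 0.7", {
  set.seed(4)
  signals <- lapply(1:3, function(i) 1 + 0.5 * sin(seq_len(120) / (2 + i)) +
                      rnorm(120, sd = 0.05))
  centers <- rbind(c(8, 8), c(8, 22), c(22, 15))
  mov <- make_blob_movie(centers = centers, signals = signals, noise_sd = 2,
                         seed = 4)
  rois <- segment_rois(mov, seed_quantile = 0.97, grow_threshold = 0.5)
  expect_length(rois, 3)
  truth <- lapply(seq_len(3), function(j) {
    px <- NULL
    for (r in 1:30) for (ci in 1:30)
      if (exp(-((r - centers[j, 1])^2 + (ci - centers[j, 2])^2) / (2 * 1.5^2))
          >= 0.05) px <- rbind(px, c(r, ci))
    roi_mask(px, j)
  })
  m <- match_rois(rois, truth)
  expect_equal(nrow(m), 3L)
  expect_true(all(m$jaccard >= 0.7))
  # masks pairwise disjoint
  keys <- unlist(lapply(rois, function(m_) paste(m_$pixels[, 1], m_$pixels[, 2])))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("identical signals at separated locations give two ROIs", {
  sig <- 1 + 0.5 * sin(seq_len(120) / 4)
  mov <- make_blob_movie(centers = rbind(c(8, 8), c(22, 22)),
                         signals = list(sig, sig), noise_sd = 1, seed = 5)
  rois <- segment_rois(mov, seed_quantile = 0.97, grow_threshold = 0.5)
  expect_length(rois, 2)
})

test_that("trace extraction equals per-frame mask means", {
  set.seed(6)
  mov <- nm_movie(array(rnorm(50 * 100, 10), dim = c(50, 10, 10)),
                  seq_len(50) / 20)
  one <- extract_traces(mov, list(roi_mask(cbind(3, 4))))[[1]]
  expect_equal(one$values, mov$pixels[, 3, 4])
  multi <- extract_traces(mov, list(roi_mask(rbind(c(1, 1), c(2, 2)))))[[1]]
  expect_equal(multi$values, (mov$pixels[, 1, 1] + mov$pixels[, 2, 2]) / 2)
  expect_error(extract_traces(mov, list(roi_mask(cbind(11, 1)))),
               "out-of-bounds")
})

test_that("dF/F normalisation follows the truncated-baseline definition", {
  ft <- seq_len(300) / 20
  raw <- rep(100, 300); raw[250] <- 150  # pulse outside the baseline window
  tr <- fluo_trace(raw, ft)
  dff <- compute_dff(tr, first_stim_onset = 12)
  expect_equal(dff$values[250], 0.5)
  expect_equal(dff$values[1], 0)
  expect_equal(dff$baseline_F, 100)

  # stimulus at 6 s truncates the 10 s baseline window
  raw2 <- c(rep(100, 119), rep(200, 181))  # jumps at frame 120 = 6 s
  dff2 <- compute_dff(fluo_trace(raw2, ft), first_stim_onset = 6)
  expect_equal(dff2$baseline_F, mean(raw2[ft < 6]))

  expect_error(compute_dff(fluo_trace(rep(0, 300), ft), 12), "baseline")
  expect_error(compute_dff(fluo_trace(rep(1, 300), ft),
                           first_stim_onset = 0.5), "pre-stimulus")
})

test_that("dF/F is invariant to positive rescaling of the raw trace", {
  set.seed(7)
  raw <- 100 + cumsum(rnorm(200))
  ft <- seq_len(200) / 20
  a <- compute_dff(fluo_trace(raw, ft), 12)
  b <- compute_dff(fluo_trace(3.7 * raw, ft), 12)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("end-to-end extraction correlates with ground-truth traces", {
  cfg <- quick_cfg(seed = 8)
  data <- simulate_dataset(cfg, movie = TRUE)
  mov <- subtract_background(data$movie$movie)
  rois <- segment_rois(mov, seed_quantile = 0.97, grow_threshold = 0.5)
  expect_gte(length(rois), 2)
  traces <- extract_traces(mov, rois)
  m <- match_rois(rois, data$movie$truth)
  for (i in seq_len(nrow(m))) {
    r <- cor(traces[[m$roi[i]]]$values,
             data$synapses$traces[[m$truth[i]]]$values)
    expect_gt(r, 0.9)
  }
})
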