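# Synthetic-data generator: spike/bout statistics, protocol, suppression
# dynamics, movie rendering, determinism.

test_that("zero bout rate yields a noise-only recording", {
  cfg <- quick_cfg(seed = 1, bout_rate = 0)
  rec <- simulate_motor_recording(cfg)
  expect_length(rec$truth$spike_times, 0)
  expect_equal(nrow(rec$truth$bouts), 0L)
  # noise plus mains only: nothing near the spike amplitude of 1
  expect_lt(max(abs(rec$trace$samples)), 0.9)
})

test_that("mean spikes per bout matches the generating rate x duration", {
  # closed form: E[spikes | bout] = within_bout_spike_rate * duration
  per_seed <- vapply(1:20, function(sd) {
    cfg <- sim_config(duration = 300, bout_rate = 0.1,
                      bout_duration_mean = 0.5,
                      within_bout_spike_rate = 40, n_steps = 0, seed = sd)
    b <- simulate_motor_recording(cfg)$truth$bouts
    c(mean(b$n_spikes), nrow(b))
  }, numeric(2))
  grand <- sum(per_seed[1, ] * per_seed[2, ]) / sum(per_seed[2, ])
  se <- sd(per_seed[1, ]) / sqrt(20)
  expect_lt(abs(grand - 20), 3 * se + 1)  # +1 for edge truncation of bouts
})

test_that("recording carries the configured 5 kHz sampling rate", {
  rec <- simulate_motor_recording(sim_preset("paper_default", seed = 1,
                                             n_steps = 2))
  expect_equal(rec$trace$rate, 5000)
})

test_that("spike times are strictly increasing and inside the recording", {
  for (sd in 1:5) {
    rec <- simulate_motor_recording(quick_cfg(seed = sd))
    st <- rec$truth$spike_times
    expect_true(all(diff(st) > 0))
    expect_true(all(st >= 0 & st <= quick_cfg(seed = sd)$duration))
  }
})

test_that("stimulus protocol alternates signs over disjoint epochs", {
  expect_equal(nrow(simulate_stimulus_protocol(quick_cfg(n_steps = 0))), 0L)
  p4 <- simulate_stimulus_protocol(quick_cfg(n_steps = 4))
  expect_equal(p4$sign, c(1, -1, 1, -1))
  p <- simulate_stimulus_protocol(sim_preset("paper_default"))
  expect_true(all(p$onset_s < p$offset_s))
  expect_true(all(p$onset_s[-1] > p$offset_s[-nrow(p)]))
})

test_that("disabling suppression gives template-plus-noise traces", {
  cfg <- quick_cfg(seed = 3, si_plateau_posterior = 0,
                   si_plateau_anterior = 0)
  data <- simulate_dataset(cfg, movie = FALSE)
  expect_true(all(data$synapses$truth$true_si == 0))
  expect_false(any(data$synapses$truth$suppressed))
  # out-of-stimulus segments fluctuate around baseline_F
  tr <- data$synapses$traces[[1]]
  pre <- tr$values[tr$frame_times < cfg$first_onset]
  expect_equal(mean(pre), cfg$baseline_F,
               tolerance = 3 * cfg$noise_sd / sqrt(length(pre)) * 5)
})

test_that("Hill gain curve evaluates to the printed value at 5 spikes", {
  # direct evaluation: 1.05 * 5 / (5 + 1.12)
  expect_equal(hill_predict(list(si_max = 1.05, n_half = 1.12), 5),
               0.858, tolerance = 5e-4)
})

test_that("suppression recovers within 100 ms of the end of a burst", {
  cfg <- quick_cfg(seed = 2, n_steps = 0, duration = 10, noise_sd = 0)
  burst <- seq(2, 2.5, by = 0.01)
  syn <- simulate_synapse_traces(cfg, spike_train(burst),
                                 simulate_stimulus_protocol(cfg))
  si <- syn$truth$true_si[1, ]
  ftm <- syn$truth$frame_times
  peak <- max(si)
  # recovery starts at the last spike (2.5 s): the frame-averaged state has
  # decayed to ~e^-1.5 of the plateau within 100 ms and is gone by 150 ms
  expect_lt(si[min(which(ftm >= 2.6))], 0.3 * peak)
  expect_lt(si[min(which(ftm >= 2.65))], 0.12 * peak)
  expect_gt(peak, 0.5 * cfg$si_plateau_posterior)
})

test_that("movie rendering respects shape, masks and trace identity", {
  cfg <- quick_cfg(seed = 4, noise_sd = 0)
  data <- simulate_dataset(cfg, movie = TRUE)
  d <- dim(data$movie$movie$pixels)
  expect_equal(d[1], length(data$synapses$traces[[1]]$frame_times))
  expect_equal(d[2:3], c(cfg$frame_height, cfg$frame_width))
  # ground-truth masks pairwise disjoint
  keys <- lapply(data$movie$truth, function(m)
    paste(m$pixels[, 1], m$pixels[, 2]))
  expect_equal(anyDuplicated(unlist(keys)), 0L)
  # noiseless extraction through the true mask reproduces the input trace
  tr <- extract_traces(data$movie$movie, data$movie$truth[1])[[1]]
  expect_gt(cor(tr$values, data$synapses$traces[[1]]$values), 0.99)
})

test_that("zero blob amplitude leaves a flat background movie", {
  cfg <- quick_cfg(seed = 5, blob_amplitude = 0, noise_sd = 0)
  data <- simulate_dataset(cfg, movie = TRUE)
  mu <- apply(data$movie$movie$pixels, 1, mean)
  expect_lt(diff(range(mu)), 1e-9)
})

test_that("identical seeds give bit-identical datasets", {
  a <- simulate_dataset(quick_cfg(seed = 9), movie = TRUE)
  b <- simulate_dataset(quick_cfg(seed = 9), movie = TRUE)
  expect_identical(a$recording$truth$spike_times,
                   b$recording$truth$spike_times)
  expect_identical(a$synapses$traces[[1]]$values,
                   b$synapses$traces[[1]]$values)
  expect_identical(a$movie$movie$pixels, b$movie$movie$pixels)
  c_ <- simulate_dataset(quick_cfg(seed = 10), movie = FALSE)
  expect_false(identical(a$recording$truth$spike_times,
                         c_$recording$truth$spike_times))
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(quick_cfg(bout_rate = -1), "bout_rate")
  expect_error(quick_cfg(frame_rate = 5), "frame_rate")
  expect_error(quick_cfg(n_half_true = 0), "n_half_true")
  expect_error(quick_cfg(noise_ar1 = 1), "noise_ar1")
})

test_that("too many blobs for the frame is a layout error", {
  cfg <- quick_cfg(seed = 1, n_synapses_posterior = 30,
                   n_synapses_anterior = 30, frame_height = 24,
                   frame_width = 24)
  data <- simulate_dataset(cfg, movie = FALSE)
  expect_error(simulate_movie(cfg, data$synapses$traces), "disjoint blobs")
})

test_that("realized SI-vs-spike-count curve tracks the generating plateaus", {
  # ground-truth (not pipeline) check: mean true SI at high spike counts
  # approaches the posterior plateau
  cfg <- sim_preset("paper_default", seed = 6, n_steps = 4)
  data <- simulate_dataset(cfg, movie = FALSE)
  st <- spike_train(data$recording$truth$spike_times)
  ftm <- data$synapses$truth$frame_times
  ns <- windowed_spike_counts(st$times, ftm, 0.05)
  si <- data$synapses$truth$true_si[1, ]   # posterior synapse
  high <- ns >= 6
  low <- ns >= 1 & ns <= 2
  expect_gt(sum(high), 10)
  # frame averaging attenuates the instantaneous plateau somewhat, but the
  # high-count mean must sit near it and well above the low-count mean
  expect_gt(mean(si[high]), 0.7 * cfg$si_plateau_posterior)
  expect_lte(max(si), cfg$si_plateau_posterior + 1e-9)
  expect_gt(mean(si[high]), mean(si[low]))
})
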