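# Trial sets, SI identities, Hill fitting, classification, polarity stats.

test_that("trial sets align frames, drop the first point and count spikes", {
  exp1 <- toy_experiment(n_trials = 6, suppression = 0, seed = 1)
  ts <- exp1$ts
  # 1 s epoch at 20 Hz: 20 in-epoch frames minus the first = 19
  expect_equal(ncol(ts$R), 19L)
  expect_equal(nrow(ts$R), 6L)

  # spikeless recording: every trial quiet, all N_s zero
  quietless <- build_trial_set(exp1$trace, exp1$protocol,
                               spike_train(numeric(0)), "posterior")
  expect_true(all(quietless$quiet))
  expect_true(all(quietless$Ns == 0))

  # N_s equals a brute-force trailing-window count
  ft <- exp1$trace$frame_times
  for (i in seq_len(nrow(exp1$protocol))) {
    idx <- which(ft > exp1$protocol$onset_s[i] &
                 ft <= exp1$protocol$offset_s[i])[-1][seq_len(ncol(ts$Ns))]
    expect_equal(as.integer(ts$Ns[i, ]),
                 count_window_brute(exp1$spikes$times, ft[idx], 0.05))
  }

  expect_error(build_trial_set(exp1$trace, exp1$protocol, exp1$spikes,
                               "anterior"), "polarity")
})

test_that("mean quiet response averages quiet trials with an SE", {
  ex <- toy_experiment(n_trials = 12, suppression = 0, noise_sd = 0.2,
                       seed = 2)
  qr <- mean_quiet_response(ex$ts)
  expect_equal(length(qr$mean), ncol(ex$ts$R))
  Q <- ex$ts$R[ex$ts$quiet, ]
  expect_equal(qr$mean, colMeans(Q))
  # sampling oracle: SE ~ sd/sqrt(n) for iid noise around a fixed template
  expect_equal(mean(qr$se), 0.2 / sqrt(qr$n_quiet), tolerance = 0.25)

  no_quiet <- ex$ts
  no_quiet$quiet[] <- FALSE
  expect_error(mean_quiet_response(no_quiet), "untestable")
})

test_that("suppression index satisfies the 0 / 1 / >1 identities", {
  R_o <- rep(1, 10)
  expect_equal(suppression_index(R_o, R_o)$si, rep(0, 10))
  expect_equal(suppression_index(R_o, rep(0, 10))$si, rep(1, 10))
  expect_equal(suppression_index(R_o, rep(-0.2, 10))$si, rep(1.2, 10))
  # negative SI when the motor-trial response is larger
  expect_equal(suppression_index(1, 1.5)$si, -0.5)
  # invariance to common positive rescaling
  set.seed(3)
  ro <- runif(20, 0.5, 2); rm_ <- rnorm(20)
  expect_equal(suppression_index(ro, rm_)$si,
               suppression_index(3 * ro, 3 * rm_)$si, tolerance = 1e-12)
  # floor guard marks low-R_o frames invalid rather than dividing
  g <- suppression_index(c(1, 0.01, 1), c(0, 0, 0), floor = 0.1)
  expect_equal(g$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(g$si[2]))
  expect_error(suppression_index(rep(0.01, 3), rep(0, 3), floor = 0.1),
               "floor")
})

test_that("pooled SI-vs-N table matches a brute-force group-by", {
  ex <- toy_experiment(n_trials = 12, suppression = 0.6, seed = 4)
  prof <- si_profiles(ex$ts)
  pooled <- pool_si_vs_spikes(prof)
  ok <- prof$valid & is.finite(prof$si)
  df <- data.frame(n = prof$ns[ok], si = prof$si[ok])
  for (nv in unique(df$n)) {
    expect_equal(pooled$groups$mean_si[pooled$groups$n == nv],
                 mean(df$si[df$n == nv]))
  }
  expect_equal(nrow(pooled$points), nrow(df))
  # pooling concatenates across profiles rather than averaging per synapse
  two <- pool_si_vs_spikes(list(prof, prof))
  expect_equal(nrow(two$points), 2 * nrow(df))
})

test_that("Hill fit recovers exact parameters from noiseless points", {
  n <- 0:10
  pts <- data.frame(n = n, si = 1.05 * n / (n + 1.12))
  fit <- fit_hill(pts)
  expect_equal(fit$si_max, 1.05, tolerance = 1e-4)
  expect_equal(fit$n_half, 1.12, tolerance = 1e-4)
  expect_equal(hill_predict(fit, 5), 1.05 * 5 / 6.12, tolerance = 1e-4)
  # half-maximal suppression at N_1/2 by definition
  expect_equal(hill_predict(fit, fit$n_half), fit$si_max / 2,
               tolerance = 1e-6)
  # monotone increasing and bounded by si_max
  pred <- hill_predict(fit, seq(0, 50, by = 0.5))
  expect_true(all(diff(pred) > 0))
  expect_true(all(pred < fit$si_max))
  expect_equal(hill_predict(fit, 0), 0)
  expect_error(fit_hill(data.frame(n = c(0, 1), si = c(0, 0.5))),
               "distinct")
})

test_that("classification is one-tailed on coincidence partitions", {
  # no motor spikes at all -> no coincident population -> untestable
  ex0 <- toy_experiment(n_trials = 6, suppression = 0, seed = 5)
  ts0 <- build_trial_set(ex0$trace, ex0$protocol, spike_train(numeric(0)),
                         "posterior")
  expect_equal(classify_synapse(ts0)$label, "untestable")

  # strong true suppression is detected
  exs <- toy_experiment(n_trials = 12, suppression = 1, noise_sd = 0.1,
                        seed = 6)
  cls <- classify_synapse(exs$ts)
  expect_equal(cls$label, "suppressed")
  expect_lt(cls$p, 0.01)
  expect_equal(cls$n_coincident + cls$n_noncoincident, length(exs$ts$R))
})

test_that("classifier has high power and nominal size on toy experiments", {
  # power: true SI = 1, default-ish noise, >= 10 overlapping trials
  hits <- vapply(1:100, function(sd)
    classify_synapse(toy_experiment(n_trials = 12, suppression = 1,
                                    noise_sd = 0.15, seed = sd)$ts)$label ==
      "suppressed", logical(1))
  expect_gte(mean(hits), 0.9)

  # size: white-noise nulls stay at or below ~alpha (binomial slack)
  false_pos <- vapply(101:400, function(sd)
    classify_synapse(toy_experiment(n_trials = 12, suppression = 0,
                                    noise_sd = 0.15, seed = sd)$ts)$label ==
      "suppressed", logical(1))
  expect_lte(mean(false_pos), 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
})

test_that("Mann-Whitney agrees with small-instance enumeration", {
  # exact one-tailed p for tiny samples, enumerated by brute force
  x <- c(1.1, 2.3); y <- c(3.1, 4.5, 5.0)
  perms <- combn(5, 2)
  vals <- c(x, y)
  stat <- function(ix) sum(rank(vals)[ix])  # rank-sum of group 1
  obs <- stat(1:2)
  p_enum <- mean(apply(perms, 2, stat) <= obs)
  wt <- wilcox.test(x, y, alternative = "less", exact = TRUE)
  expect_equal(wt$p.value, p_enum)
  cmp <- compare_polarity_groups(x, y)
  expect_equal(cmp$p, wilcox.test(x, y)$p.value)
})

test_that("polarity binomial null matches the printed arithmetic", {
  expect_equal(round(polarity_binomial_test(0.7, 16), 3), 0.003)
  expect_equal(polarity_binomial_test(0.42, 0), 1)
  expect_equal(polarity_binomial_test(1, 12), 1)
  expect_equal(suppression_probability(29, 41), 29 / 41)
})

test_that("polarity group comparison detects the printed difference", {
  set.seed(10)
  same <- rnorm(16, 1, 0.1)
  expect_gt(compare_polarity_groups(same, same + rnorm(16, 0, 1e-6))$p, 0.05)

  # groups at the printed means/SEMs (per-synapse SD = SEM * sqrt(n))
  hits <- vapply(1:200, function(sd) {
    set.seed(sd)
    post <- rnorm(16, 1.20, 0.03 * sqrt(16))
    ant <- rnorm(13, 0.54, 0.07 * sqrt(13))
    compare_polarity_groups(post, ant)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  single <- compare_polarity_groups(1.2, c(0.5, 0.6))
  expect_true(is.finite(single$p))
  expect_true(single$wide_uncertainty)
})

test_that("raising generator suppression raises measured mean SI", {
  mean_si_at <- function(scale) {
    cfg <- quick_cfg(seed = 12, si_plateau_posterior = scale,
                     si_plateau_anterior = scale / 2)
    data <- simulate_dataset(cfg, movie = FALSE)
    spikes <- spike_train(data$recording$truth$spike_times)
    tr <- compute_dff(data$synapses$traces[[1]],
                      first_stim_onset = min(data$protocol$onset_s))
    ts <- build_trial_set(tr, data$protocol, spikes, "posterior")
    synapse_si_summary(si_profiles(ts), "mean_si")
  }
  lo <- mean_si_at(0.4); hi <- mean_si_at(1.6)
  expect_gt(hi, lo)
})
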