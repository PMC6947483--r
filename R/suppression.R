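# Core inference: trial-aligned suppression index, SI-vs-spike-count
# pooling, Hill fitting, coincidence/Mann-Whitney classification of
# suppressed synapses, and polarity statistics.

#' Build a trial-aligned set of stimulus responses for one synapse
#'
#' For each stimulus epoch of the synapse's polarity, extracts the dF/F
#' frames whose timestamps fall in `(onset, offset]`, dropping the first
#' in-epoch frame (its timing within the frame interval is uncertain).
#' Trials are truncated to a common frame count. For every kept frame the
#' motor spike count in the preceding `ns_window` seconds (N_s) and a
#' coincidence flag (>= 1 spike in the frame's own preceding frame
#' interval) are recorded. A trial is quiet when no spike falls in
#' `(onset - quiet_guard, offset]`.
#'
#' @param trace a dF/F `fluo_trace`
#' @param epochs data.frame with `onset_s`, `offset_s`, `sign` (+1 deflects
#'   the cupula posteriorly, -1 anteriorly)
#' @param spikes a `spike_train` on the same clock
#' @param polarity `"posterior"` (responds to +1 epochs) or `"anterior"`
#' @param ns_window trailing window for N_s (s); default 0.05 s
#' @param quiet_guard extension of the quiet test before onset (s)
#' @param pre_window pre-onset window kept for noise estimation (s)
#' @return object of class `trial_set`
#' @export
build_trial_set <- function(trace, epochs, spikes,
                            polarity = c("posterior", "anterior"),
                            ns_window = 0.05, quiet_guard = 0.05,
                            pre_window = 0.5) {
  stopifnot(inherits(trace, "fluo_trace"), inherits(spikes, "spike_train"))
  polarity <- match.arg(polarity)
  want_sign <- if (polarity == "posterior") 1 else -1
  ep <- epochs[epochs$sign == want_sign, , drop = FALSE]
  if (nrow(ep) == 0L)
    stop(sprintf("no epochs of %s polarity", polarity), call. = FALSE)
  ft <- trace$frame_times
  if (min(ep$onset_s) < ft[1L] || max(ep$offset_s) > ft[length(ft)])
    stop("epochs extend beyond the trace span", call. = FALSE)
  all_counts <- downsample_to_frames(spikes, ft)
  idx_list <- lapply(seq_len(nrow(ep)), function(i) {
    idx <- which(ft > ep$onset_s[i] & ft <= ep$offset_s[i])
    if (length(idx) > 1L) idx[-1L] else integer(0)
  })
  n_keep <- min(lengths(idx_list))
  if (n_keep < 1L)
    stop("epochs contain no usable frames after dropping the first",
         call. = FALSE)
  pre_list <- lapply(seq_len(nrow(ep)), function(i)
    which(ft > ep$onset_s[i] - pre_window & ft <= ep$onset_s[i]))
  n_pre <- min(lengths(pre_list))
  take <- function(v, idx, n) v[idx[seq_len(n)]]
  rows <- function(lst, f, n) {                   # trials x frames matrix
    t(matrix(vapply(lst, f, numeric(n)), nrow = n))
  }
  R <- rows(idx_list, function(idx) take(trace$values, idx, n_keep), n_keep)
  Ns <- rows(idx_list, function(idx)
    as.numeric(windowed_spike_counts(spikes$times, take(ft, idx, n_keep),
                                     ns_window)), n_keep)
  coinc <- rows(idx_list, function(idx)
    as.numeric(take(all_counts, idx, n_keep) >= 1L), n_keep) > 0
  Rpre <- if (n_pre >= 1L) {
    rows(pre_list, function(idx)
      trace$values[utils::tail(idx, n_pre)], n_pre)
  } else matrix(numeric(0), nrow = nrow(ep), ncol = 0L)
  quiet <- vapply(seq_len(nrow(ep)), function(i)
    .count_in(spikes$times, ep$onset_s[i] - quiet_guard, ep$offset_s[i]) == 0L,
    logical(1))
  structure(list(
    roi_label = trace$roi_label, polarity = polarity,
    onsets = ep$onset_s,
    rel_times = take(ft, idx_list[[1L]], n_keep) - ep$onset_s[1L],
    R = R, Ns = Ns, coincident = coinc, Rpre = Rpre, quiet = quiet,
    frame_dt = stats::median(diff(ft))), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %s, %d trials (%d quiet) x %d frames\n",
              x$polarity, nrow(x$R), sum(x$quiet), ncol(x$R)))
  invisible(x)
}

#' Frame-wise mean response over quiet trials
#'
#' R_o(t): the average dF/F at each aligned frame over trials without motor
#' activity, with its frame-wise standard error.
#'
#' @param ts a `trial_set`
#' @return list with `mean`, `se` and `n_quiet`
#' @export
mean_quiet_response <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  nq <- sum(ts$quiet)
  if (nq == 0L)
    stop("no quiet trials: R_o undefined, synapse untestable", call. = FALSE)
  Q <- ts$R[ts$quiet, , drop = FALSE]
  m <- colMeans(Q)
  se <- if (nq > 1L) apply(Q, 2L, stats::sd) / sqrt(nq) else rep(NA_real_, ncol(Q))
  list(mean = m, se = se, n_quiet = nq)
}

#' Suppression index of one trial against the quiet-trial mean
#'
#' SI(t) = (R_o(t) - R_m(t)) / R_o(t): 0 means no suppression, 1 full
#' suppression of the evoked response, > 1 suppression below the
#' pre-stimulus baseline; negative values occur when the response during
#' motor activity is larger than the quiet average. Frames where
#' `R_o < floor` are marked invalid (division guard).
#'
#' @param R_o quiet-trial mean response (dF/F per aligned frame)
#' @param R_m single-trial response, same length
#' @param floor minimum R_o for a defined SI (dF/F)
#' @return list with `si` (NA where invalid) and logical `valid`
#' @export
suppression_index <- function(R_o, R_m, floor = 0) {
  if (length(R_o) != length(R_m))
    stop("R_o and R_m must have equal length", call. = FALSE)
  valid <- is.finite(R_o) & R_o >= floor & R_o > 0
  if (!any(valid))
    stop("all frames invalid: R_o below floor everywhere", call. = FALSE)
  si <- rep(NA_real_, length(R_o))
  si[valid] <- (R_o[valid] - R_m[valid]) / R_o[valid]
  list(si = si, valid = valid)
}

#' Per-trial SI profiles for one synapse
#'
#' Computes R_o from quiet trials, a division-guard floor (by default three
#' times the pre-stimulus noise SD of R_o, estimated from the quiet trials'
#' pre-onset frames), and the SI series of every non-quiet (motor) trial
#' together with its per-frame N_s.
#'
#' @param ts a `trial_set`
#' @param floor division guard (dF/F); `NULL` uses 3 x the pre-stimulus
#'   noise SD of R_o
#' @return object of class `si_profile`: `si`, `ns`, `valid` matrices over
#'   motor trials, plus `R_o` and `floor`
#' @export
si_profiles <- function(ts, floor = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  qr <- mean_quiet_response(ts)
  if (is.null(floor)) {
    nq <- qr$n_quiet
    pre <- ts$Rpre[ts$quiet, , drop = FALSE]
    sd_pre <- if (length(pre) > 1L) stats::sd(as.numeric(pre)) else NA_real_
    floor <- if (is.finite(sd_pre)) 3 * sd_pre / sqrt(nq) else 0
  }
  motor <- which(!ts$quiet)
  if (length(motor) == 0L)
    stop("no motor-overlapping trials: SI cannot be computed", call. = FALSE)
  si <- matrix(NA_real_, length(motor), ncol(ts$R))
  valid <- matrix(FALSE, length(motor), ncol(ts$R))
  for (k in seq_along(motor)) {
    s <- suppression_index(qr$mean, ts$R[motor[k], ], floor)
    si[k, ] <- s$si
    valid[k, ] <- s$valid
  }
  structure(list(roi_label = ts$roi_label, polarity = ts$polarity,
                 R_o = qr$mean, floor = floor, si = si,
                 ns = ts$Ns[motor, , drop = FALSE], valid = valid),
            class = "si_profile")
}

#' Pool SI-versus-spike-count points across synapses
#'
#' Collects all valid (N_s, SI) pairs from a list of SI profiles (pooling
#' across synapses, not averaging per synapse first) and summarises them by
#' integer N_s with group means and SEMs.
#'
#' @param profiles list of `si_profile`
#' @return list with `points` (data.frame `n`, `si`) and `groups`
#'   (data.frame `n`, `mean_si`, `sem_si`, `n_points`)
#' @export
pool_si_vs_spikes <- function(profiles) {
  if (inherits(profiles, "si_profile")) profiles <- list(profiles)
  pts <- do.call(rbind, lapply(profiles, function(p) {
    ok <- p$valid & is.finite(p$si)
    data.frame(n = as.integer(p$ns[ok]), si = p$si[ok])
  }))
  if (is.null(pts) || nrow(pts) == 0L)
    stop("no valid (N_s, SI) points to pool", call. = FALSE)
  agg <- lapply(split(pts$si, pts$n), function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v)))
  groups <- data.frame(n = as.integer(names(agg)),
                       mean_si = vapply(agg, `[[`, 0, "mean"),
                       sem_si = vapply(agg, `[[`, 0, "sem"),
                       n_points = vapply(agg, `[[`, 0, "n"),
                       row.names = NULL)
  list(points = pts, groups = groups[order(groups$n), ])
}

#' Fit the Hill gain curve SI(N_s) = SI_max * N_s / (N_s + N_1/2)
#'
#' Least-squares fit over pooled (N_s, SI) points with si_max >= 0 and
#' n_half > 0 enforced; parameter standard errors come from the fit
#' covariance. Points may be weighted (e.g. by inverse variance).
#'
#' @param points data.frame with columns `n` and `si` (pooled points), or
#'   the list returned by [pool_si_vs_spikes()]
#' @param weights optional per-point weights
#' @return object of class `hill_fit` with `si_max`, `n_half`, `se_si_max`,
#'   `se_n_half`, `rss`, `n_points`
#' @export
fit_hill <- function(points, weights = NULL) {
  if (is.list(points) && !is.data.frame(points) && !is.null(points$points))
    points <- points$points
  if (length(unique(points$n)) < 3L)
    stop("need at least 3 distinct N_s values to fit", call. = FALSE)
  df <- data.frame(n = points$n, si = points$si)
  if (is.null(weights)) weights <- rep(1, nrow(df))
  si_max0 <- max(0.1, stats::quantile(df$si[df$n >= stats::median(df$n)],
                                      0.5, names = FALSE), na.rm = TRUE)
  fit <- tryCatch(
    minpack.lm::nlsLM(si ~ si_max * n / (n + n_half), data = df,
                      start = list(si_max = si_max0, n_half = 1),
                      lower = c(si_max = 0, n_half = 1e-8),
                      weights = weights,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf(
      "Hill fit failed to converge: %s (n_points=%d, si range %.3g..%.3g)",
      conditionMessage(e), nrow(df), min(df$si), max(df$si)), call. = FALSE))
  co <- summary(fit)$coefficients
  structure(list(si_max = co["si_max", "Estimate"],
                 n_half = co["n_half", "Estimate"],
                 se_si_max = co["si_max", "Std. Error"],
                 se_n_half = co["n_half", "Std. Error"],
                 rss = sum(stats::residuals(fit)^2),
                 n_points = nrow(df)), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> SI_max = %.3f +/- %.3f, N_1/2 = %.3f +/- %.3f (n = %d)\n",
              x$si_max, x$se_si_max, x$n_half, x$se_n_half, x$n_points))
  invisible(x)
}

#' Predict SI from a Hill gain curve
#'
#' @param fit a `hill_fit`, or a list/named vector with `si_max`, `n_half`
#' @param n_spikes spike counts (>= 0)
#' @return predicted SI, `si_max * n / (n + n_half)`
#' @export
hill_predict <- function(fit, n_spikes) {
  stopifnot(all(n_spikes >= 0))
  si_max <- if (inherits(fit, "hill_fit")) fit$si_max else fit[["si_max"]]
  n_half <- if (inherits(fit, "hill_fit")) fit$n_half else fit[["n_half"]]
  si_max * n_spikes / (n_spikes + n_half)
}

#' Classify a synapse as suppressed or unaffected
#'
#' Three steps: (1) pool all in-stimulus frames across trials (first frames
#' were already dropped when the trial set was built); (2) partition them
#' into frames that coincide with at least one motor spike in their
#' preceding frame interval and frames that do not; (3) compare the two
#' populations with a one-tailed Mann-Whitney U test (alternative:
#' coincident population lower). The synapse is `suppressed` when
#' p < alpha, `untestable` when either population is empty.
#'
#' @param ts a `trial_set`
#' @param alpha significance level, default 0.05
#' @return object of class `synapse_classification` with `label`, `U`,
#'   `p`, `n_coincident`, `n_noncoincident`
#' @export
classify_synapse <- function(ts, alpha = 0.05) {
  stopifnot(inherits(ts, "trial_set"))
  vals <- as.numeric(t(ts$R))
  coin <- as.logical(t(ts$coincident))
  x <- vals[coin]; y <- vals[!coin]
  if (length(x) == 0L || length(y) == 0L) {
    res <- list(label = "untestable", U = NA_real_, p = NA_real_,
                n_coincident = length(x), n_noncoincident = length(y),
                alpha = alpha)
    return(structure(res, class = "synapse_classification"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", correct = TRUE))
  label <- if (wt$p.value < alpha) "suppressed" else "unaffected"
  structure(list(label = label, U = unname(wt$statistic), p = wt$p.value,
                 n_coincident = length(x), n_noncoincident = length(y),
                 alpha = alpha),
            class = "synapse_classification")
}

#' @export
print.synapse_classification <- function(x, ...) {
  cat(sprintf("<synapse_classification> %s (U = %s, p = %s; %d vs %d frames)\n",
              x$label, format(x$U), format.pval(x$p),
              x$n_coincident, x$n_noncoincident))
  invisible(x)
}

#' Per-synapse SI summary during motor activity
#'
#' Summarises an SI profile over frames that overlap motor activity
#' (N_s >= 1): either the mean SI (`"mean_si"`) or the maximum (`"max_si"`).
#'
#' @param profile an `si_profile`
#' @param statistic summary to compute
#' @return scalar summary, NA when no motor-overlapping valid frame exists
#' @export
synapse_si_summary <- function(profile, statistic = c("mean_si", "max_si")) {
  statistic <- match.arg(statistic)
  ok <- profile$valid & is.finite(profile$si) & profile$ns >= 1L
  if (!any(ok)) return(NA_real_)
  v <- profile$si[ok]
  if (statistic == "mean_si") mean(v) else max(v)
}

#' Probability of suppression from classification counts
#'
#' @param n_suppressed number of synapses classified suppressed
#' @param n_total total synapses tested
#' @return the fraction `n_suppressed / n_total`
#' @export
suppression_probability <- function(n_suppressed, n_total) {
  stopifnot(n_total > 0, n_suppressed >= 0, n_suppressed <= n_total)
  n_suppressed / n_total
}

#' Polarity-blind null probability that a whole group is suppressed
#'
#' Under the null hypothesis that polarity has no bearing on suppression,
#' each synapse is suppressed independently with the overall probability
#' `p_overall`; the probability that all `n_group` synapses of one polarity
#' are suppressed is then `p_overall ^ n_group`.
#'
#' @param p_overall overall suppression probability in [0, 1]
#' @param n_group group size (>= 0)
#' @return the null probability
#' @export
polarity_binomial_test <- function(p_overall, n_group) {
  stopifnot(p_overall >= 0, p_overall <= 1, n_group >= 0)
  p_overall^n_group
}

#' Compare per-synapse SI between polarity groups
#'
#' Takes per-synapse summary statistics (see [synapse_si_summary()]) for
#' the posterior- and anterior-polarity groups, and returns group means
#' with SEMs and a two-sided Mann-Whitney p value.
#'
#' @param si_posterior numeric vector, one summary per posterior synapse
#' @param si_anterior numeric vector, one summary per anterior synapse
#' @return list with group means, SEMs, `p`, group sizes, and
#'   `wide_uncertainty` flag when a group has a single member
#' @export
compare_polarity_groups <- function(si_posterior, si_anterior) {
  si_posterior <- si_posterior[is.finite(si_posterior)]
  si_anterior <- si_anterior[is.finite(si_anterior)]
  if (length(si_posterior) == 0L || length(si_anterior) == 0L)
    stop("both polarity groups must be non-empty", call. = FALSE)
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  wt <- suppressWarnings(
    stats::wilcox.test(si_posterior, si_anterior, alternative = "two.sided"))
  list(mean_posterior = mean(si_posterior), sem_posterior = sem(si_posterior),
       mean_anterior = mean(si_anterior), sem_anterior = sem(si_anterior),
       n_posterior = length(si_posterior), n_anterior = length(si_anterior),
       U = unname(wt$statistic), p = wt$p.value,
       wide_uncertainty = length(si_posterior) < 2L || length(si_anterior) < 2L)
}
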