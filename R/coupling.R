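# Motor-to-sensory coupling statistics: per-bout fluorescence integrals
# versus spike counts, and the signed cross-correlation lag between a
# fluorescence trace and the frame-downsampled spike train.

#' Integrate a fluorescence trace over one swim bout
#'
#' Computes the trapezoidal integral of dF/F over the bout window extended
#' by `extension` seconds (to capture indicator decay), referenced to the
#' mean dF/F in the `pre_window` seconds preceding the bout. Suppression of
#' spontaneous release yields a negative integral.
#'
#' @param trace a dF/F `fluo_trace`
#' @param bout one-row data.frame (or list) with `start`, `end`, `n_spikes`
#' @param extension post-bout extension of the integration window (s)
#' @param pre_window pre-bout window for the reference level (s)
#' @return data.frame with `start`, `end`, `n_spikes`, `fluo_integral`
#' @export
bout_fluorescence_integral <- function(trace, bout, extension = 0.5,
                                       pre_window = 0.5) {
  stopifnot(inherits(trace, "fluo_trace"))
  ft <- trace$frame_times
  if (bout$start < ft[1L] || bout$end > ft[length(ft)])
    stop("bout lies outside the trace span", call. = FALSE)
  pre <- ft >= bout$start - pre_window & ft < bout$start
  ref <- if (any(pre)) mean(trace$values[pre]) else 0
  win <- ft >= bout$start & ft <= min(bout$end + extension, ft[length(ft)])
  integ <- .trapz(ft[win], trace$values[win] - ref)
  data.frame(start = bout$start, end = bout$end,
             n_spikes = as.integer(bout$n_spikes), fluo_integral = integ)
}

#' Per-bout integrals for a whole bout table
#'
#' @param trace a dF/F `fluo_trace`
#' @param bouts data.frame from [segment_bouts()]
#' @inheritParams bout_fluorescence_integral
#' @return data.frame, one row per bout inside the trace span
#' @export
bout_metrics <- function(trace, bouts, extension = 0.5, pre_window = 0.5) {
  ft <- trace$frame_times
  keep <- bouts$start >= ft[1L] & bouts$end <= ft[length(ft)]
  rows <- lapply(which(keep), function(i)
    bout_fluorescence_integral(trace, bouts[i, ], extension, pre_window))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pearson correlation between per-bout spike counts and integrals
#'
#' @param metrics data.frame with `n_spikes` and `fluo_integral`
#' @return Pearson r
#' @export
spike_count_integral_correlation <- function(metrics) {
  if (nrow(metrics) < 3L)
    stop("need at least 3 bouts", call. = FALSE)
  if (stats::sd(metrics$n_spikes) == 0 || stats::sd(metrics$fluo_integral) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(metrics$n_spikes, metrics$fluo_integral)
}

#' Cross-correlation between a trace and per-frame spike counts
#'
#' Computes the Pearson correlation at every integer frame lag in
#' `[-max_lag, max_lag]`, each on the mean-subtracted overlapping segments
#' so |r| <= 1 holds exactly. A positive lag means the fluorescence change
#' FOLLOWS the spikes. The extremum reported is the most negative
#' correlation, the relevant feature for suppression.
#'
#' @param trace a `fluo_trace` (or numeric vector of per-frame values)
#' @param frame_counts per-frame spike counts, same length
#' @param max_lag maximum lag (s); at least one frame interval
#' @return list of class `xcorr_result` with `lags` (s), `correlation`,
#'   `extremum_lag` (s) and `extremum_value`
#' @export
cross_correlate_lag <- function(trace, frame_counts, max_lag = 0.5) {
  values <- if (inherits(trace, "fluo_trace")) trace$values else as.numeric(trace)
  dt <- if (inherits(trace, "fluo_trace")) {
    stats::median(diff(trace$frame_times))
  } else 1
  n <- length(values)
  if (length(frame_counts) != n)
    stop("trace and frame_counts must have equal length", call. = FALSE)
  if (stats::sd(values) == 0 || stats::sd(frame_counts) == 0)
    stop("correlation undefined: constant input", call. = FALSE)
  lmax <- max(1L, floor(max_lag / dt + 1e-9))
  lags <- (-lmax):lmax
  rr <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- frame_counts[seq_len(n - l)]
      b <- values[seq_len(n - l) + l]
    } else {
      a <- frame_counts[seq_len(n + l) - l]
      b <- values[seq_len(n + l)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  imin <- which.min(rr)
  structure(list(lags = lags * dt, correlation = rr,
                 extremum_lag = lags[imin] * dt, extremum_value = rr[imin]),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr_result> extremum r = %.3f at lag %+.3f s\n",
              x$extremum_value, x$extremum_lag))
  invisible(x)
}
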