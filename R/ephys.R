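# Motor-nerve electrophysiology: filtering, spike extraction, rate
# estimation and swim-bout segmentation.

#' Construct an extracellular voltage trace
#'
#' @param samples numeric vector of voltages (V)
#' @param rate sampling rate (samples/s), > 0
#' @param t0 time of the first sample (s)
#' @return an object of class `ephys_trace`
#' @export
ephys_trace <- function(samples, rate, t0 = 0) {
  stopifnot(is.numeric(samples), is.numeric(rate), length(rate) == 1L,
            rate > 0, is.finite(t0))
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Sample times of an ephys trace
#' @param trace an `ephys_trace`
#' @return numeric vector of sample times (s)
#' @export
trace_times <- function(trace) {
  trace$t0 + seq_along(trace$samples) / trace$rate
}

#' Construct a spike train
#'
#' @param times spike times (s); must be strictly increasing
#' @param source_rate sampling rate of the trace the spikes came from
#' @return an object of class `spike_train`
#' @export
spike_train <- function(times, source_rate = NA_real_) {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  structure(list(times = times, source_rate = source_rate),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes\n", length(x$times)))
  invisible(x)
}

# Biquad 50 Hz notch (constrained direct-form coefficients), applied
# forward-backward so it adds no phase delay.
.notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter a motor-nerve recording
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass between
#' `band[1]` and `band[2]` Hz followed by a zero-phase notch at `notch` Hz
#' to remove mains interference. Zero-phase filtering is used so that spike
#' times are not delayed relative to the imaging clock.
#'
#' @param trace an `ephys_trace`; its rate must be at least 2.5 times the
#'   upper band edge so the pass-band is below Nyquist
#' @param band numeric length-2, band-pass corners (Hz); default 300-1000 Hz
#' @param notch notch centre frequency (Hz); `NA` disables the notch
#' @param notch_q notch quality factor (centre / -3 dB width)
#' @param order Butterworth order of the one-way band-pass
#' @return filtered `ephys_trace`, same length and clock
#' @export
filter_motor_trace <- function(trace, band = c(300, 1000), notch = 50,
                               notch_q = 30, order = 2) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$rate < 2.5 * band[2])
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 trace$rate, band[2]), call. = FALSE)
  if (!all(is.finite(trace$samples)))
    stop("trace contains non-finite samples", call. = FALSE)
  # reflect-pad both ends so filtfilt start-up transients stay outside the
  # recording
  npad <- min(length(trace$samples) - 1L, round(0.5 * trace$rate))
  x <- trace$samples - mean(trace$samples)   # the band-pass has no DC gain
  xp <- c(2 * x[1L] - rev(x[seq_len(npad) + 1L]), x,
          2 * x[length(x)] - rev(x[length(x) - seq_len(npad)]))
  bp <- signal::butter(order, band / (trace$rate / 2), type = "pass")
  y <- signal::filtfilt(bp, xp)
  if (!is.na(notch)) {
    nc <- .notch_coefs(notch, trace$rate, notch_q)
    y <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), y)
  }
  ephys_trace(y[npad + seq_along(x)], trace$rate, trace$t0)
}

#' Detect spikes by threshold crossing
#'
#' The threshold is `threshold_mads` times a robust estimate of the noise
#' scale (median absolute deviation scaled to the Gaussian SD, i.e.
#' MAD x 1.4826). A spike is registered at each upward crossing; crossings
#' closer together than `refractory` are merged, and each spike time is
#' aligned to the rectified peak following its crossing (zero-phase
#' filtering smears waveforms symmetrically, so the crossing sample itself
#' sits slightly before the spike).
#'
#' @param trace a filtered `ephys_trace`
#' @param threshold_mads threshold in units of the robust noise SD
#' @param refractory merge window (s); crossings within it count as one spike
#' @param polarity `"abs"` detects on the rectified trace (default, robust to
#'   either spike sign), `"pos"`/`"neg"` on the raw or inverted trace
#' @return a `spike_train` with peak-aligned spike times
#' @export
detect_spikes <- function(trace, threshold_mads = 5, refractory = 0.002,
                          polarity = c("abs", "pos", "neg")) {
  stopifnot(inherits(trace, "ephys_trace"))
  polarity <- match.arg(polarity)
  x <- switch(polarity, abs = abs(trace$samples), pos = trace$samples,
              neg = -trace$samples)
  if (!all(is.finite(x))) stop("non-finite samples in trace", call. = FALSE)
  # robust noise SD from the signed trace (MAD about zero, Gaussian-scaled):
  # insensitive to the spikes themselves
  noise_sd <- stats::mad(trace$samples, center = 0)
  thr <- threshold_mads * noise_sd
  n <- length(x)
  if (n < 2L || thr <= 0) return(spike_train(numeric(0), trace$rate))
  up <- which(x[-1L] >= thr & x[-n] < thr) + 1L
  if (length(up) == 0L) return(spike_train(numeric(0), trace$rate))
  # keep a crossing only if it falls at least `refractory` after the last
  # kept one (merges the multiple crossings of one biphasic waveform), then
  # align the spike time to the rectified peak within the merge window —
  # the crossing sample itself is biased early by the zero-phase filter's
  # acausal precursor
  ref_n <- max(1L, round(refractory * trace$rate))
  kept <- up[1L]
  last <- up[1L]
  for (i in up[-1L]) {
    if (i - last > ref_n) {
      kept <- c(kept, i)
      last <- i
    }
  }
  peaks <- vapply(kept, function(i) {
    j <- i:min(n, i + ref_n)
    j[which.max(x[j])]
  }, integer(1))
  spike_train(trace$t0 + peaks / trace$rate, trace$rate)
}

#' Smoothed instantaneous spike rate
#'
#' Convolves the spike train with a unit-area Gaussian kernel
#' (sigma = FWHM / 2.3548) and samples it on a regular grid, giving a rate
#' in spikes/s whose time integral equals the spike count (up to edge
#' truncation).
#'
#' @param spikes a `spike_train`
#' @param fwhm kernel full width at half maximum (s); default 0.1 s
#' @param grid_rate sampling rate of the output grid (samples/s)
#' @param t_start,t_end grid extent (s); default spans the spikes +- 4 sigma
#' @return list with `times` and `rate` (spikes/s)
#' @export
spike_rate <- function(spikes, fwhm = 0.1, grid_rate = 100,
                       t_start = NULL, t_end = NULL) {
  stopifnot(inherits(spikes, "spike_train"), fwhm > 0, grid_rate > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  st <- spikes$times
  if (is.null(t_start)) t_start <- if (length(st)) min(st) - 4 * sigma else 0
  if (is.null(t_end)) t_end <- if (length(st)) max(st) + 4 * sigma else 1
  times <- seq(t_start, t_end, by = 1 / grid_rate)
  rate <- numeric(length(times))
  for (s in st) {
    i1 <- max(1L, floor((s - 5 * sigma - t_start) * grid_rate) + 1L)
    i2 <- min(length(times), ceiling((s + 5 * sigma - t_start) * grid_rate) + 1L)
    if (i1 <= i2)
      rate[i1:i2] <- rate[i1:i2] + stats::dnorm(times[i1:i2], mean = s, sd = sigma)
  }
  list(times = times, rate = rate)
}

#' Group spikes into swim bouts
#'
#' A bout is a maximal run of spikes whose consecutive inter-spike intervals
#' are all `<= max_isi`. Bout start/end are the first/last spike times.
#'
#' @param spikes a `spike_train`
#' @param max_isi maximum within-bout inter-spike interval (s); default 0.2 s
#' @return data.frame with columns `start`, `end`, `n_spikes`
#' @export
segment_bouts <- function(spikes, max_isi = 0.2) {
  stopifnot(inherits(spikes, "spike_train"), max_isi > 0)
  st <- spikes$times
  if (length(st) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0)))
  brk <- c(0L, which(diff(st) > max_isi), length(st))
  starts <- st[brk[-length(brk)] + 1L]
  ends <- st[brk[-1L]]
  data.frame(start = starts, end = ends,
             n_spikes = as.integer(diff(brk)))
}

#' Down-sample a spike train to per-frame counts
#'
#' Counts spikes in each frame's preceding interval `(t[k-1], t[k]]`, the
#' half-open convention under which a spike exactly at a frame timestamp
#' belongs to that frame. Frame timestamps mark the end of each frame's
#' exposure.
#'
#' @param spikes a `spike_train`
#' @param frame_times strictly increasing frame timestamps (s)
#' @param t0 left edge of the first frame interval; defaults to
#'   `frame_times[1]` minus the median frame interval
#' @return integer vector of per-frame spike counts
#' @export
downsample_to_frames <- function(spikes, frame_times, t0 = NULL) {
  stopifnot(inherits(spikes, "spike_train"), length(frame_times) >= 1L)
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("frame_times must be strictly increasing", call. = FALSE)
  if (is.null(t0)) {
    dt <- if (length(frame_times) > 1L) stats::median(diff(frame_times)) else 1
    t0 <- frame_times[1L] - dt
  }
  edges <- c(t0, frame_times)
  st <- spikes$times
  if (length(st) == 0L) return(integer(length(frame_times)))
  bin <- findInterval(st, edges, left.open = TRUE)
  bin <- bin[bin >= 1L & bin <= length(frame_times)]
  tabulate(bin, nbins = length(frame_times))
}
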