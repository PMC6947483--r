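# Internal helpers shared across modules.

#' Count spikes in a trailing window before each query time
#'
#' For each time in `at`, counts spikes falling in the half-open interval
#' `(at - window, at]`. Used both for the 50-ms spike-count windows of the
#' suppression analysis and for per-frame coincidence flags.
#'
#' @param spike_times sorted numeric vector of spike times (s)
#' @param at numeric vector of query times (s)
#' @param window trailing window length (s), > 0
#' @return integer vector, same length as `at`
#' @export
windowed_spike_counts <- function(spike_times, at, window) {
  stopifnot(is.numeric(window), length(window) == 1L, window > 0)
  if (length(spike_times) == 0L) return(integer(length(at)))
  # spikes s with at - window < s <= at
  hi <- findInterval(at, spike_times)                     # s <= at
  lo <- findInterval(at - window, spike_times)            # s <= at - window
  as.integer(hi - lo)
}

# Spikes in (a, b] for scalar bounds.
.count_in <- function(spike_times, a, b) {
  sum(spike_times > a & spike_times <= b)
}

# Trapezoidal integral of y over x.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Deterministic per-stage seed derived from a master seed, kept < 2^31.
.stage_seed <- function(seed, stage) {
  offsets <- c(motor = 101L, protocol = 211L, synapse = 307L, movie = 401L,
               noise = 503L, misc = 601L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483587)
}

.assert_cfg <- function(ok, field, msg) {
  if (!ok) stop(sprintf("invalid configuration field '%s': %s", field, msg),
                call. = FALSE)
}
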