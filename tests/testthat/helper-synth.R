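# Shared fixtures built in code: small configs and hand-made traces.

# Fast config for generator tests: short recording, few synapses.
quick_cfg <- function(...) {
  sim_preset("tiny", ...)
}

# A dF/F trace with a known constant frame rate.
flat_trace <- function(n = 100, value = 0, frame_rate = 20) {
  fluo_trace(rep(value, n), seq_len(n) / frame_rate, baseline_F = 1)
}

# Voltage trace of isolated spike waveforms at known times plus noise,
# built directly from the package's template (independent of the bout
# machinery), for detector tests.
isolated_spike_trace <- function(times, rate = 5000, duration = 10,
                                 noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  n <- round(duration * rate)
  v <- rnorm(n, sd = noise_sd)
  tmpl <- efference:::.spike_template(rate)
  pk <- which.max(abs(tmpl)) - 1L   # truth times mark the waveform peak
  for (s in times) {
    i <- round(s * rate) - pk
    idx <- i:min(n, i + length(tmpl) - 1L)
    v[idx] <- v[idx] + tmpl[seq_along(idx)]
  }
  ephys_trace(v, rate)
}

# Brute-force Pearson correlation from first principles.
pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Brute-force trailing-window spike count.
count_window_brute <- function(spikes, at, w) {
  vapply(at, function(t) sum(spikes > t - w & spikes <= t), integer(1))
}

# A minimal trial-set-like experiment: evoked step responses with optional
# suppression during spike-coincident frames; returns a trial_set via the
# public builder.
toy_experiment <- function(n_trials = 12, suppression = 0, noise_sd = 0.1,
                           frame_rate = 20, seed = 1) {
  set.seed(seed)
  step_dur <- 1; gap <- 2; first <- 12
  onsets <- first + (seq_len(n_trials) - 1) * (step_dur + gap)
  protocol <- data.frame(onset_s = onsets, offset_s = onsets + step_dur,
                         sign = 1)
  dur <- max(protocol$offset_s) + 2
  ft <- seq_len(floor(dur * frame_rate)) / frame_rate
  # motor bouts overlap every second trial
  spk <- unlist(lapply(onsets[seq(2, n_trials, by = 2)], function(o)
    sort(o + 0.2 + cumsum(rexp(20, 100)))))
  spk <- sort(spk[spk < dur])
  spikes <- spike_train(spk)
  counts <- downsample_to_frames(spikes, ft)
  evoked <- rep(0, length(ft))
  for (i in seq_len(nrow(protocol)))
    evoked[ft > protocol$onset_s[i] & ft <= protocol$offset_s[i]] <- 1
  gain <- 1 - suppression * (counts >= 1)
  values <- evoked * gain + rnorm(length(ft), sd = noise_sd)
  tr <- fluo_trace(values, ft, baseline_F = 1)
  list(trace = tr, protocol = protocol, spikes = spikes,
       ts = build_trial_set(tr, protocol, spikes, "posterior"))
}
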