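#!/usr/bin/env Rscript
# Stage 2: motor-nerve processing. Band-pass (300-1000 Hz) + 50 Hz notch
# filtering, MAD-threshold spike detection, Gaussian-smoothed spike rate
# (FWHM 100 ms) and swim-bout segmentation. Detection quality is checked
# against the generator's ground truth.

suppressMessages(library(efference))

raw <- read_ephys_csv("results/data/ephys.csv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)

filtered <- filter_motor_trace(raw)
spikes <- detect_spikes(filtered, threshold_mads = 5)
bouts <- segment_bouts(spikes, max_isi = 0.2)
rate <- spike_rate(spikes, fwhm = 0.1, grid_rate = 100,
                   t_start = 0, t_end = max(spikes$times) + 0.5)

d <- vapply(truth$spike_times, function(s) min(abs(spikes$times - s)),
            numeric(1))
fp <- vapply(spikes$times, function(s) min(abs(truth$spike_times - s)),
             numeric(1))
cat(sprintf("detected %d spikes (%d true): recovery %.1f%%, false positives %d\n",
            length(spikes$times), length(truth$spike_times),
            100 * mean(d <= 1e-3), sum(fp > 1e-3)))
cat(sprintf("%d bouts, %.1f spikes/bout (truth: %d bouts, %.1f)\n",
            nrow(bouts), mean(bouts$n_spikes), nrow(truth$bouts),
            mean(truth$bouts$n_spikes)))

dir.create("results", showWarnings = FALSE)
data.table::fwrite(data.frame(time_s = spikes$times), "results/spikes.csv")
data.table::fwrite(bouts, "results/bouts.csv")
data.table::fwrite(data.frame(time_s = rate$times, rate_hz = rate$rate),
                   "results/spike_rate.csv")
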