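# Simulation configuration and presets.

#' Simulation configuration for the synthetic-data generator
#'
#' Defaults are the `paper_default` study conditions: a 5 kHz nerve
#' recording imaged at 20 Hz, bout-structured motor spiking, 16
#' posterior-polarity and 13 anterior-polarity suppressed synapses, and a
#' Hill gain curve with pooled SI_max = 1.05 and N_1/2 = 1.12 spikes.
#'
#' `si_plateau_posterior` / `si_plateau_anterior` are calibration constants
#' of the preset: the per-group measured-SI plateaus that make the
#' pipeline-measured group means hit `si_mean_posterior` /
#' `si_mean_anterior` while the pooled Hill fit recovers `si_max_true`.
#' They are derived from the group-mean targets and the mean unit gain
#' during motor-overlapping frames (see the methods vignette) and live in
#' the preset, not in analysis code.
#'
#' @param ephys_rate nerve sampling rate (samples/s)
#' @param frame_rate imaging frame rate (frames/s), 20-50
#' @param duration recording duration (s); `NULL` derives it from the
#'   stimulus protocol plus a 3 s tail
#' @param bout_rate rate of the exponential inter-bout renewal process
#'   (bouts/s)
#' @param within_bout_spike_rate mean within-bout spike rate (spikes/s);
#'   spiking is a renewal process with a 3 ms refractory period
#' @param bout_duration_mean mean bout duration (s); bout durations are
#'   gamma-distributed with shape 4
#' @param spike_snr spike template peak over noise SD
#' @param mains_amplitude 50 Hz mains component, in spike-peak units
#' @param n_synapses_posterior,n_synapses_anterior synapse counts per
#'   polarity group
#' @param si_max_true,n_half_true pooled Hill ground truth (SI_max, N_1/2)
#' @param si_mean_posterior,si_mean_anterior target pipeline-measured group
#'   mean SI during motor-overlapping frames
#' @param si_plateau_posterior,si_plateau_anterior calibrated per-group
#'   measured-SI plateaus (see Details)
#' @param drive_n_half calibrated half-count of the internal Hill drive
#'   (spikes); set below `n_half_true` to offset the indicator-lag
#'   attenuation of single-spike windows, so the measured pooled curve
#'   recovers `n_half_true`
#' @param spont_evoked_ratio spontaneous release rate relative to the
#'   evoked rate; sets the evoked dF/F (= 1/ratio) and the headroom for
#'   SI > 1
#' @param recovery_tau exponential recovery time constant of the
#'   suppression state once the 50 ms spike window empties (s); 17 ms gives
#'   >= 90 % recovery of the gain within 100 ms of the last spike
#' @param onset_delay suppression onset delay after a spike (s), sub-frame
#' @param indicator_tau_decay single-exponential indicator decay (s)
#' @param noise_sd additive trace noise SD (dF/F units)
#' @param noise_ar1 lag-one autocorrelation of the trace noise (AR(1));
#'   0 gives white noise
#' @param baseline_F baseline fluorescence (camera counts)
#' @param n_steps number of pressure steps (alternating +/-)
#' @param step_duration,inter_step_interval stimulus timing (s)
#' @param first_onset onset of the first step (s); leaves a pre-stimulus
#'   baseline window
#' @param frame_height,frame_width movie dimensions (pixels)
#' @param blob_sigma spatial SD of a synapse blob (pixels)
#' @param blob_amplitude peak blob brightness (counts)
#' @param background_counts static movie background (counts)
#' @param seed master seed; all stage seeds derive from it
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(ephys_rate = 5000, frame_rate = 20, duration = NULL,
                       bout_rate = 0.8, within_bout_spike_rate = 110,
                       bout_duration_mean = 0.5, spike_snr = 10,
                       mains_amplitude = 0.2,
                       n_synapses_posterior = 16, n_synapses_anterior = 13,
                       si_max_true = 1.05, n_half_true = 1.12,
                       si_mean_posterior = 1.20, si_mean_anterior = 0.54,
                       si_plateau_posterior = 1.990,
                       si_plateau_anterior = 0.810,
                       drive_n_half = 1.12,
                       spont_evoked_ratio = 1.1, recovery_tau = 0.017,
                       onset_delay = 0.01, indicator_tau_decay = 0.03,
                       noise_sd = 0.15, noise_ar1 = 0.15, baseline_F = 200,
                       n_steps = 40, step_duration = 1,
                       inter_step_interval = 2, first_onset = 12,
                       frame_height = 72, frame_width = 60,
                       blob_sigma = 1.5, blob_amplitude = 300,
                       background_counts = 100, seed = 1L) {
  if (is.null(duration))
    duration <- first_onset +
      n_steps * (step_duration + inter_step_interval) + 3
  cfg <- list(ephys_rate = ephys_rate, frame_rate = frame_rate,
              duration = duration, bout_rate = bout_rate,
              within_bout_spike_rate = within_bout_spike_rate,
              bout_duration_mean = bout_duration_mean,
              spike_snr = spike_snr, mains_amplitude = mains_amplitude,
              n_synapses_posterior = n_synapses_posterior,
              n_synapses_anterior = n_synapses_anterior,
              si_max_true = si_max_true, n_half_true = n_half_true,
              si_mean_posterior = si_mean_posterior,
              si_mean_anterior = si_mean_anterior,
              si_plateau_posterior = si_plateau_posterior,
              si_plateau_anterior = si_plateau_anterior,
              drive_n_half = drive_n_half,
              spont_evoked_ratio = spont_evoked_ratio,
              recovery_tau = recovery_tau, onset_delay = onset_delay,
              indicator_tau_decay = indicator_tau_decay,
              noise_sd = noise_sd, noise_ar1 = noise_ar1,
              baseline_F = baseline_F, n_steps = n_steps,
              step_duration = step_duration,
              inter_step_interval = inter_step_interval,
              first_onset = first_onset, frame_height = frame_height,
              frame_width = frame_width, blob_sigma = blob_sigma,
              blob_amplitude = blob_amplitude,
              background_counts = background_counts,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' @param cfg list of configuration fields
#' @return the config, invisibly; errors name the offending field
#' @export
validate_sim_config <- function(cfg) {
  .assert_cfg(cfg$ephys_rate > 0, "ephys_rate", "must be > 0")
  .assert_cfg(cfg$frame_rate >= 20 && cfg$frame_rate <= 50, "frame_rate",
              "must lie in [20, 50] frames/s")
  .assert_cfg(cfg$frame_rate <= cfg$ephys_rate, "frame_rate",
              "must not exceed ephys_rate")
  .assert_cfg(cfg$duration > 0, "duration", "must be > 0")
  .assert_cfg(cfg$bout_rate >= 0, "bout_rate", "must be >= 0")
  .assert_cfg(cfg$within_bout_spike_rate > 0, "within_bout_spike_rate",
              "must be > 0")
  .assert_cfg(cfg$bout_duration_mean > 0, "bout_duration_mean", "must be > 0")
  .assert_cfg(cfg$spike_snr > 0, "spike_snr", "must be > 0")
  .assert_cfg(cfg$n_synapses_posterior >= 0, "n_synapses_posterior",
              "must be >= 0")
  .assert_cfg(cfg$n_synapses_anterior >= 0, "n_synapses_anterior",
              "must be >= 0")
  .assert_cfg(cfg$si_max_true >= 0, "si_max_true", "must be >= 0")
  .assert_cfg(cfg$n_half_true > 0, "n_half_true", "must be > 0")
  .assert_cfg(cfg$drive_n_half > 0, "drive_n_half", "must be > 0")
  .assert_cfg(cfg$si_plateau_posterior >= 0, "si_plateau_posterior",
              "must be >= 0")
  .assert_cfg(cfg$si_plateau_anterior >= 0, "si_plateau_anterior",
              "must be >= 0")
  .assert_cfg(cfg$spont_evoked_ratio > 0, "spont_evoked_ratio",
              "must be > 0")
  .assert_cfg(cfg$recovery_tau > 0, "recovery_tau", "must be > 0")
  .assert_cfg(cfg$indicator_tau_decay > 0, "indicator_tau_decay",
              "must be > 0")
  .assert_cfg(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  .assert_cfg(cfg$noise_ar1 >= 0 && cfg$noise_ar1 < 1, "noise_ar1",
              "must lie in [0, 1)")
  .assert_cfg(cfg$baseline_F > 0, "baseline_F", "must be > 0")
  .assert_cfg(cfg$n_steps >= 0, "n_steps", "must be >= 0")
  .assert_cfg(cfg$step_duration > 0, "step_duration", "must be > 0")
  .assert_cfg(cfg$first_onset > 1, "first_onset",
              "must leave > 1 s of pre-stimulus baseline")
  invisible(cfg)
}

#' Named simulation presets
#'
#' `paper_default` is the standard study condition (29 suppressed synapses,
#' 16 posterior + 13 anterior). `tiny` is a 2-synapse, ~60 s dataset for
#' fast smoke runs. `null` has zero true suppression (plateaus 0) and is
#' used for classification-size studies.
#'
#' @param name preset name
#' @param seed master seed
#' @param ... overrides passed to [sim_config()]
#' @return a `sim_config`
#' @export
sim_preset <- function(name = c("paper_default", "tiny", "null"),
                       seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    paper_default = list(),
    tiny = list(n_synapses_posterior = 1, n_synapses_anterior = 1,
                n_steps = 14, frame_height = 24, frame_width = 24),
    null = list(si_plateau_posterior = 0, si_plateau_anterior = 0))
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, c(list(seed = seed), args))
}
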