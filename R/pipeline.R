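# End-to-end orchestration: synthetic generation -> spike extraction ->
# imaging -> coupling -> suppression statistics, with a machine-readable
# report.

#' Simulate a complete dataset
#'
#' Runs the generator stages on a common clock: motor recording, stimulus
#' protocol, synapse traces and (optionally) the rendered movie.
#'
#' @param cfg a `sim_config`
#' @param movie render the fluorescence movie as well?
#' @return list with `recording`, `protocol`, `synapses`, and `movie`
#'   (NULL when not rendered)
#' @export
simulate_dataset <- function(cfg, movie = TRUE) {
  rec <- simulate_motor_recording(cfg)
  protocol <- simulate_stimulus_protocol(cfg)
  syn <- simulate_synapse_traces(cfg, spike_train(rec$truth$spike_times),
                                 protocol)
  mov <- if (movie) simulate_movie(cfg, syn$traces) else NULL
  list(recording = rec, protocol = protocol, synapses = syn, movie = mov)
}

# Pearson cross-correlation at integer frame lags restricted to frames for
# which `keep` is TRUE, pairing only frames within the same contiguous kept
# segment. Used to estimate the motor->sensory lag outside stimulus epochs.
.xcorr_masked <- function(values, counts, keep, dt, max_lag) {
  n <- length(values)
  seg <- cumsum(!keep)            # constant within a kept run
  lmax <- max(1L, floor(max_lag / dt + 1e-9))
  lags <- (-lmax):lmax
  rr <- vapply(lags, function(l) {
    if (l >= 0) { i <- seq_len(n - l); j <- i + l } else {
      j <- seq_len(n + l); i <- j - l
    }
    ok <- keep[i] & keep[j] & seg[i] == seg[j]
    if (sum(ok) < 10L) return(NA_real_)
    a <- counts[i[ok]]; b <- values[j[ok]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  imin <- which.min(rr)
  list(lags = lags * dt, correlation = rr, extremum_lag = lags[imin] * dt,
       extremum_value = rr[imin])
}

# Data-driven polarity call: mean dF/F during positive-sign epochs versus
# negative-sign epochs (first in-epoch frame excluded, as elsewhere).
.infer_polarity <- function(trace, protocol) {
  ft <- trace$frame_times
  m <- vapply(c(1, -1), function(sg) {
    ep <- protocol[protocol$sign == sg, , drop = FALSE]
    idx <- unlist(lapply(seq_len(nrow(ep)), function(i) {
      k <- which(ft > ep$onset_s[i] & ft <= ep$offset_s[i])
      if (length(k) > 1L) k[-1L] else integer(0)
    }))
    mean(trace$values[idx])
  }, numeric(1))
  if (m[1L] >= m[2L]) "posterior" else "anterior"
}

#' Run the full analysis pipeline on synthetic (or loaded) data
#'
#' Executes generation, nerve filtering and spike detection, bout
#' segmentation, (optionally) movie segmentation and trace extraction,
#' dF/F normalisation, motor-coupling statistics, and the suppression
#' analysis: classification of every synapse, pooled Hill fit over
#' suppressed synapses, polarity group comparison and the polarity-blind
#' binomial null probability.
#'
#' @param cfg a `sim_config`
#' @param use_movie analyse traces extracted from the rendered movie
#'   (`TRUE`, full pipeline) or the generator's trace stage directly
#' @param data optional pre-simulated dataset from [simulate_dataset()];
#'   when NULL it is simulated from `cfg`
#' @param threshold_mads spike threshold in robust noise SDs
#' @param max_isi bout segmentation gap (s)
#' @param seed_quantile,grow_threshold ROI segmentation parameters
#' @param alpha classification significance level
#' @param ns_window trailing spike-count window (s)
#' @param max_lag cross-correlation lag range (s)
#' @param outdir optional directory for report JSON and per-stage CSVs
#' @return report list of class `nm_report`
#' @export
run_pipeline <- function(cfg, use_movie = TRUE, data = NULL,
                         threshold_mads = 5, max_isi = 0.2,
                         seed_quantile = 0.95, grow_threshold = 0.5,
                         alpha = 0.05, ns_window = 0.05, max_lag = 0.3,
                         outdir = NULL) {
  if (is.null(data)) data <- simulate_dataset(cfg, movie = use_movie)
  protocol <- data$protocol
  first_onset <- if (nrow(protocol)) min(protocol$onset_s) else Inf

  # --- ephys stage -------------------------------------------------------
  filtered <- filter_motor_trace(data$recording$trace)
  spikes <- detect_spikes(filtered, threshold_mads = threshold_mads)
  bouts <- segment_bouts(spikes, max_isi = max_isi)

  # --- imaging stage -----------------------------------------------------
  if (use_movie) {
    mov <- subtract_background(data$movie$movie)
    masks <- segment_rois(mov, seed_quantile = seed_quantile,
                          grow_threshold = grow_threshold)
    if (length(masks) == 0L)
      stop("imaging stage: no ROIs segmented", call. = FALSE)
    raw_traces <- extract_traces(mov, masks)
    matches <- match_rois(masks, data$movie$truth)
  } else {
    raw_traces <- data$synapses$traces
    matches <- data.frame(roi = seq_along(raw_traces),
                          truth = seq_along(raw_traces),
                          jaccard = rep(1, length(raw_traces)))
  }
  dff <- lapply(raw_traces, compute_dff, first_stim_onset = first_onset)

  # --- coupling stage ----------------------------------------------------
  ft <- dff[[1L]]$frame_times
  frame_counts <- downsample_to_frames(spikes, ft)
  dt <- stats::median(diff(ft))
  in_epoch <- rep(FALSE, length(ft))
  for (i in seq_len(nrow(protocol)))
    in_epoch <- in_epoch | (ft > protocol$onset_s[i] - 0.5 &
                            ft <= protocol$offset_s[i] + 0.5)
  free_bouts <- bouts[vapply(seq_len(nrow(bouts)), function(i)
    !any(protocol$onset_s < bouts$end[i] + 0.5 &
         protocol$offset_s > bouts$start[i] - 0.5), logical(1)) &
    bouts$start > ft[1L] + 0.5 & bouts$end < ft[length(ft)] - 0.5, ,
    drop = FALSE]

  # --- suppression stage -------------------------------------------------
  per_syn <- lapply(seq_along(dff), function(k) {
    tr <- dff[[k]]
    pol <- .infer_polarity(tr, protocol)
    ts <- build_trial_set(tr, protocol, spikes, polarity = pol,
                          ns_window = ns_window)
    cls <- classify_synapse(ts, alpha = alpha)
    prof <- mean_si <- max_si <- NULL
    if (cls$label == "suppressed" && sum(ts$quiet) >= 1L &&
        any(!ts$quiet)) {
      prof <- si_profiles(ts)
      mean_si <- synapse_si_summary(prof, "mean_si")
      max_si <- synapse_si_summary(prof, "max_si")
    }
    xc <- tryCatch(
      .xcorr_masked(tr$values, frame_counts, !in_epoch, dt, max_lag),
      error = function(e) NULL)
    bm <- if (nrow(free_bouts) >= 3L) bout_metrics(tr, free_bouts) else NULL
    r_bout <- if (!is.null(bm) && nrow(bm) >= 3L &&
                  stats::sd(bm$n_spikes) > 0 && stats::sd(bm$fluo_integral) > 0)
      spike_count_integral_correlation(bm) else NA_real_
    list(roi = tr$roi_label, polarity = pol, label = cls$label,
         p = cls$p, mean_si = mean_si %||% NA_real_,
         max_si = max_si %||% NA_real_, profile = prof,
         xcorr_lag = if (is.null(xc)) NA_real_ else xc$extremum_lag,
         xcorr_r = if (is.null(xc)) NA_real_ else xc$extremum_value,
         bout_integral_r = r_bout)
  })

  tab <- data.frame(
    roi = vapply(per_syn, `[[`, 0, "roi"),
    polarity = vapply(per_syn, `[[`, "", "polarity"),
    label = vapply(per_syn, `[[`, "", "label"),
    p = vapply(per_syn, `[[`, 0, "p"),
    mean_si = vapply(per_syn, `[[`, 0, "mean_si"),
    max_si = vapply(per_syn, `[[`, 0, "max_si"),
    xcorr_lag = vapply(per_syn, `[[`, 0, "xcorr_lag"),
    bout_integral_r = vapply(per_syn, `[[`, 0, "bout_integral_r"))

  profiles <- Filter(Negate(is.null), lapply(per_syn, `[[`, "profile"))
  hill <- NULL
  pooled <- NULL
  if (length(profiles) > 0L) {
    pooled <- pool_si_vs_spikes(profiles)
    hill <- tryCatch(fit_hill(pooled$points), error = function(e) NULL)
  }

  sup <- tab$label == "suppressed"
  tested <- tab$label != "untestable"
  contingency <- as.data.frame(table(polarity = tab$polarity,
                                     label = tab$label))
  groups <- NULL
  g_post <- tab$mean_si[sup & tab$polarity == "posterior"]
  g_ant <- tab$mean_si[sup & tab$polarity == "anterior"]
  if (sum(is.finite(g_post)) && sum(is.finite(g_ant)))
    groups <- compare_polarity_groups(g_post, g_ant)
  p_overall <- if (sum(tested)) suppression_probability(sum(sup), sum(tested))
    else NA_real_
  n_post_tested <- sum(tested & tab$polarity == "posterior")
  null_p <- if (is.finite(p_overall))
    polarity_binomial_test(p_overall, n_post_tested) else NA_real_

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json"); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)

  report <- structure(list(
    synapses = tab, contingency = contingency,
    n_suppressed = sum(sup), n_tested = sum(tested),
    p_overall = p_overall, polarity_null_p = null_p,
    hill = hill, pooled_groups = if (is.null(pooled)) NULL else pooled$groups,
    group_comparison = groups,
    coupling = list(
      median_bout_integral_r = stats::median(tab$bout_integral_r, na.rm = TRUE),
      mean_xcorr_lag_suppressed = mean(tab$xcorr_lag[sup], na.rm = TRUE)),
    ephys = list(n_spikes = length(spikes$times), n_bouts = nrow(bouts)),
    roi_matches = matches,
    provenance = list(config_hash = cfg_hash, seed = cfg$seed,
                      package_version = as.character(
                        utils::packageVersion("efference")))),
    class = "nm_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nm_report <- function(x, ...) {
  cat(sprintf("<nm_report> %d/%d synapses suppressed", x$n_suppressed,
              x$n_tested))
  if (!is.null(x$hill))
    cat(sprintf("; Hill SI_max = %.2f, N_1/2 = %.2f", x$hill$si_max,
                x$hill$n_half))
  if (!is.null(x$group_comparison))
    cat(sprintf("; SI %.2f (post) vs %.2f (ant)",
                x$group_comparison$mean_posterior,
                x$group_comparison$mean_anterior))
  cat("\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` plus per-stage CSVs (`synapses.csv`,
#' `pooled_si.csv`) under `outdir`.
#'
#' @param report an `nm_report`
#' @param outdir output directory (created if missing)
#' @return `outdir`, invisibly
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- unclass(report)
  out$synapses <- NULL; out$roi_matches <- NULL; out$pooled_groups <- NULL
  if (!is.null(out$hill)) out$hill <- unclass(out$hill)
  jsonlite::write_json(out, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  data.table::fwrite(report$synapses, file.path(outdir, "synapses.csv"))
  if (!is.null(report$pooled_groups))
    data.table::fwrite(report$pooled_groups,
                       file.path(outdir, "pooled_si.csv"))
  invisible(outdir)
}

#' Empirical size of the suppressed/unaffected classification
#'
#' Generates synapses with zero true suppression (null preset: motor
#' spikes present but uncoupled to release, evoked responses intact, AR(1)
#' trace noise), classifies each with [classify_synapse()] and returns the
#' fraction labelled suppressed. Synapses are generated in batches, each
#' batch with a fresh bout-structured spike train.
#'
#' @param n_synapses total null synapses
#' @param alpha significance level passed to the classifier
#' @param seed master seed
#' @param batch_size synapses per spike-train batch (split between the two
#'   polarities)
#' @param ... overrides forwarded to the null preset
#' @return list with `fraction_suppressed`, `labels`, `n`
#' @export
classification_size_study <- function(n_synapses = 1000, alpha = 0.05,
                                      seed = 1L, batch_size = 100L, ...) {
  n_batches <- ceiling(n_synapses / batch_size)
  labels <- character(0)
  for (bi in seq_len(n_batches)) {
    nb <- min(batch_size, n_synapses - length(labels))
    npo <- ceiling(nb / 2); nan <- nb - npo
    cfg <- sim_preset("null", seed = seed + 7919L * bi,
                      n_synapses_posterior = npo,
                      n_synapses_anterior = nan, ...)
    set.seed(.stage_seed(cfg$seed, "motor"))
    st <- .simulate_bout_spike_times(cfg)
    spikes <- spike_train(st$spikes)
    protocol <- simulate_stimulus_protocol(cfg)
    syn <- simulate_synapse_traces(cfg, spikes, protocol)
    first_onset <- min(protocol$onset_s)
    for (k in seq_along(syn$traces)) {
      tr <- compute_dff(syn$traces[[k]], first_stim_onset = first_onset)
      ts <- build_trial_set(tr, protocol, spikes,
                            polarity = syn$truth$polarity[k])
      labels <- c(labels, classify_synapse(ts, alpha = alpha)$label)
    }
  }
  list(fraction_suppressed = mean(labels == "suppressed"),
       labels = labels, n = length(labels))
}

#' Write a self-contained synthetic fixture to disk
#'
#' `tiny` (2 synapses, ~1 min) runs the full pipeline in seconds;
#' `paper_default` mirrors the standard study condition (16 posterior + 13
#' anterior suppressed-capable synapses); `null` has zero true suppression.
#'
#' @param name fixture name
#' @param outdir output directory
#' @param seed master seed
#' @return list of written paths, invisibly
#' @export
make_fixture <- function(name = c("tiny", "paper_default", "null"),
                         outdir, seed = 1L) {
  name <- match.arg(name)
  cfg <- sim_preset(name, seed = seed)
  data <- simulate_dataset(cfg, movie = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    movie = write_movie_tiff(data$movie$movie,
                             file.path(outdir, "movie.tif")),
    ephys = write_ephys_csv(data$recording$trace,
                            file.path(outdir, "ephys.csv")),
    protocol = write_protocol_csv(data$protocol,
                                  file.path(outdir, "protocol.csv")),
    traces = write_traces_csv(data$synapses$traces,
                              file.path(outdir, "traces.csv")),
    truth = write_truth_json(
      list(spike_times = data$recording$truth$spike_times,
           bouts = data$recording$truth$bouts,
           polarity = data$synapses$truth$polarity,
           suppressed = data$synapses$truth$suppressed,
           plateau = data$synapses$truth$plateau,
           masks = lapply(data$movie$truth, function(m)
             list(label = m$label, pixels = m$pixels))),
      file.path(outdir, "ground_truth.json")))
  invisible(paths)
}
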