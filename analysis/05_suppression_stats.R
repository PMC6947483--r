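#!/usr/bin/env Rscript
# Stage 5: the core inference. Trial-aligned suppression indices,
# three-step coincidence/Mann-Whitney classification, pooled SI-vs-N_s
# Hill fit, polarity contingency and group comparison, and the
# polarity-blind binomial null.

suppressMessages(library(efference))

dff <- read_traces_csv("results/traces_dff.csv")
spikes <- spike_train(data.table::fread("results/spikes.csv")$time_s)
protocol <- read_protocol_csv("results/data/protocol.csv")

per_syn <- lapply(dff, function(tr) {
  # polarity from the data: which step sign evokes the larger response
  resp <- vapply(c(1, -1), function(sg) {
    ep <- protocol[protocol$sign == sg, ]
    idx <- unlist(lapply(seq_len(nrow(ep)), function(i) {
      k <- which(tr$frame_times > ep$onset_s[i] &
                 tr$frame_times <= ep$offset_s[i])
      if (length(k) > 1) k[-1] else integer(0)
    }))
    mean(tr$values[idx])
  }, numeric(1))
  pol <- if (resp[1] >= resp[2]) "posterior" else "anterior"
  ts <- build_trial_set(tr, protocol, spikes, polarity = pol)
  cls <- classify_synapse(ts, alpha = 0.05)
  prof <- NULL
  if (cls$label == "suppressed" && sum(ts$quiet) >= 1 && any(!ts$quiet))
    prof <- si_profiles(ts)
  list(roi = tr$roi_label, polarity = pol, label = cls$label, p = cls$p,
       profile = prof,
       mean_si = if (is.null(prof)) NA else synapse_si_summary(prof),
       max_si = if (is.null(prof)) NA else synapse_si_summary(prof, "max_si"))
})

tab <- data.frame(
  roi = sapply(per_syn, `[[`, "roi"),
  polarity = sapply(per_syn, `[[`, "polarity"),
  label = sapply(per_syn, `[[`, "label"),
  p = sapply(per_syn, `[[`, "p"),
  mean_si = sapply(per_syn, `[[`, "mean_si"),
  max_si = sapply(per_syn, `[[`, "max_si"))
print(table(tab$polarity, tab$label))

n_sup <- sum(tab$label == "suppressed")
n_tested <- sum(tab$label != "untestable")
p_overall <- suppression_probability(n_sup, n_tested)
cat(sprintf("suppressed: %d/%d = %.0f%%\n", n_sup, n_tested,
            100 * p_overall))

profiles <- Filter(Negate(is.null), lapply(per_syn, `[[`, "profile"))
pooled <- pool_si_vs_spikes(profiles)
hill <- fit_hill(pooled$points)
cat(sprintf("Hill fit over %d pooled points: SI_max = %.2f +/- %.2f, N_1/2 = %.2f +/- %.2f\n",
            hill$n_points, hill$si_max, hill$se_si_max, hill$n_half,
            hill$se_n_half))
cat(sprintf("predicted suppression for a 5-spike burst: %.0f%%\n",
            100 * hill_predict(hill, 5)))

g <- compare_polarity_groups(
  tab$mean_si[tab$label == "suppressed" & tab$polarity == "posterior"],
  tab$mean_si[tab$label == "suppressed" & tab$polarity == "anterior"])
cat(sprintf("group SI: posterior %.2f +/- %.3f (n=%d) vs anterior %.2f +/- %.3f (n=%d), Mann-Whitney p = %.2g\n",
            g$mean_posterior, g$sem_posterior, g$n_posterior,
            g$mean_anterior, g$sem_anterior, g$n_anterior, g$p))
n_post <- sum(tab$polarity == "posterior" & tab$label != "untestable")
cat(sprintf("polarity-blind null: P(all %d posterior suppressed) = %.3f\n",
            n_post, polarity_binomial_test(p_overall, n_post)))

data.table::fwrite(tab, "results/synapse_classification.csv")
data.table::fwrite(pooled$groups, "results/pooled_si_vs_ns.csv")
data.table::fwrite(data.frame(si_max = hill$si_max, se_si_max = hill$se_si_max,
                              n_half = hill$n_half, se_n_half = hill$se_n_half,
                              rss = hill$rss, n_points = hill$n_points),
                   "results/hill_fit.csv")
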