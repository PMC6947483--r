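#!/usr/bin/env Rscript
# Stage 1: generate the standard synthetic dataset (16 posterior + 13
# anterior suppressed synapses, bout-structured fictive swimming, 20 Hz
# imaging at 5 kHz nerve sampling) and write it to results/data/ as TIFF,
# CSV and JSON. Later stages read only these files.

suppressMessages(library(efference))

seed <- 1L
outdir <- "results/data"
paths <- make_fixture("paper_default", outdir, seed = seed)

cfg <- sim_preset("paper_default", seed = seed)
truth <- jsonlite::read_json(file.path(outdir, "ground_truth.json"),
                             simplifyVector = TRUE)
cat(sprintf("wrote %s:\n", outdir))
cat(sprintf("  %d true spikes in %d bouts over %.0f s\n",
            length(truth$spike_times), nrow(truth$bouts), cfg$duration))
cat(sprintf("  %d synapses (%d posterior, %d anterior), movie %dx%d @ %g Hz\n",
            length(truth$polarity), sum(truth$polarity == "posterior"),
            sum(truth$polarity == "anterior"), cfg$frame_height,
            cfg$frame_width, cfg$frame_rate))
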