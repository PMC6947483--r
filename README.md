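# efference

Quantitative analysis of efference-copy inhibition at hair-cell synapses of
the zebrafish lateral line.

When a fish swims, its own body motion stimulates the lateral-line
neuromasts that normally detect external water flow. A copy of the motor
command is forwarded to cholinergic efferents that inhibit hair-cell
synapses during swimming, filtering out self-generated stimuli.
`efference` implements the full quantitative workflow for studying this
circuit *in vivo*: from raw motor-nerve voltage and fluorescence movies
(iGluSnFR glutamate imaging of hair-cell ribbon synapses, GCaMP calcium
imaging of efferent axons) to per-synapse suppression statistics — together
with a ground-truthed synthetic-data generator, so every stage is testable
without access to raw recordings.

## The statistics at the core

For each mechanical-stimulus trial, the **suppression index** compares the
response during motor activity with the average quiet-trial response
R<sub>o</sub>(t):

    SI(t) = (R_o(t) − R_m(t)) / R_o(t)

SI = 0 means no suppression, SI = 1 full suppression of the evoked
response, and SI > 1 suppression below the pre-stimulus baseline
(spontaneous release is blocked as well). Pooled across suppressed
synapses, SI follows the motor spike count N<sub>s</sub> in the preceding
50 ms through a **Hill gain curve**

    SI(N_s) = SI_max · N_s / (N_s + N_1/2)

with SI<sub>max</sub> ≈ 1.05 and N<sub>1/2</sub> ≈ 1.12 spikes: a couple of
motor spikes already silence the synapse half-maximally.

Each synapse is classified **suppressed** or **unaffected** in three
steps: pool all in-stimulus dF/F points (dropping each trial's first
frame), partition them by coincidence with ≥ 1 motor spike in the
preceding frame interval, and compare the partitions with a one-tailed
Mann-Whitney U test at α = 0.05. Polarity statistics (posterior- versus
anterior-tuned hair cells) then test whether the efference copy targets
one direction channel selectively.

## Worked example

```r
library(efference)

cfg <- sim_preset("paper_default", seed = 1)   # 16 posterior + 13 anterior synapses
report <- run_pipeline(cfg, use_movie = TRUE)  # simulate -> spikes -> ROIs -> SI
report
#> <nm_report> 29/29 synapses suppressed; Hill SI_max = 1.05, N_1/2 = 0.54; SI 1.17 (post) vs 0.53 (ant)
```

(The half-count from a single dataset is noisy; averaged over 20 seeds the
fit recovers N_1/2 within a few percent of the generating 1.12 — see
`scripts/acceptance.R`.)

The report carries per-synapse classifications, the pooled Hill fit with
standard errors, polarity group means ± SEM with the Mann-Whitney p value,
the polarity-blind binomial null probability, coupling statistics (per-bout
fluorescence integrals versus spike counts; cross-correlation lag), and
provenance (config hash, seed, package version).

The numbered scripts under `analysis/` run the same workflow stage by
stage on files (TIFF movie, CSV ephys/protocol), writing tables under
`results/`. On the standard dataset they print, among other things:

```
detected 4468 spikes (4468 true): recovery 100.0%, false positives 0
segmented 29 ROIs for 29 true synapses; 29 matched, median Jaccard 1.00
max anti-correlation r = -0.86 at a lag of 50 ms (one frame at 20 Hz)
Hill fit over 8265 pooled points: SI_max = 1.05 +/- 0.02, N_1/2 = 0.54 +/- 0.07
group SI: posterior 1.17 +/- 0.005 (n=16) vs anterior 0.53 +/- 0.011 (n=13), Mann-Whitney p = 2.9e-08
```

## Vignette

`vignettes/methods.Rmd` documents the model assumptions, the generator's
calibration, numerical choices and known limitations.
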