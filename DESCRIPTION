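Package: efference
Title: Quantifying Efference-Copy Suppression at Lateral-Line Hair-Cell Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for efference-copy inhibition in the zebrafish
    lateral line: filtering and spike extraction from motor-nerve recordings,
    correlation-seeded ROI segmentation and dF/F extraction from fluorescence
    movies, motor-to-sensory coupling statistics, the per-frame suppression
    index with Hill-model gain curves, Mann-Whitney classification of
    suppressed synapses, and polarity statistics. Includes a ground-truthed
    synthetic-data generator emulating bout-structured motor spiking,
    indicator kinetics and spike-count-dependent suppression, so that every
    stage of the pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    data.table,
    tiff,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
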