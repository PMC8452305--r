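Package: purkinjetrain
Title: Simple and Complex Spike Analysis of Developing Purkinje Cell Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in vivo extracellular recordings of
    cerebellar Purkinje cells during early postnatal development.
    Classifies detected action potentials into simple spikes, complex
    spikes and doublets, computes per-cell simple-spike firing statistics
    (frequency, frequency mode, CV, CV2, pause percentage and an
    autocorrelogram-based rhythmicity index), and builds population-level
    summaries: a z-scored clusterogram, a tSNE pseudo-timeline and a
    hierarchical linkage of group-mean firing properties, with one-way
    ANOVA and Tukey-Kramer post-hoc comparisons. A synthetic spike-train
    module (renewal, burst-pause and rate-modulated Poisson generators
    with ground-truth labelled complex-spike and doublet injections)
    allows every stage to be exercised and validated without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
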