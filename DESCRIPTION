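Package: sfnet
Title: Shared-Frequency EEG Networks and Small-World Metrics for Coma Prognostication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-second functional connectivity networks from multichannel
    scalp EEG by detecting significant spectral peaks (0.5 Hz grid, 1-25 Hz) and
    linking channels that share oscillation frequencies. Computes raw and
    random-graph-normalized clustering coefficient, average path length and
    small-world index per second, averages them over 5-minute epochs and clinical
    time windows, and runs cohort-level outcome statistics (two-sample t-tests,
    Spearman correlation with CPC score, a centered sum-of-ranks composite,
    Wilcoxon rank-sum tests and ROC analysis). Includes a synthetic ICU-EEG
    generator with known shared-oscillator ground truth (normal, low-voltage,
    iso-electric, burst-suppression and periodic-discharge archetypes), a minimal
    EDF/EDF+ reader and writer, and a simulate/analyze/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pROC,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
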