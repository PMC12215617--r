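Package: kisssync
Title: Detection and Quantification of Kisspeptin Neuron Synchronization Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing and statistics pipeline for calcium activity of
    the arcuate kisspeptin (ARN-KISS) neuron population, the GnRH pulse
    generator. Processes dual-channel (calcium-dependent 465-490 nm and
    isosbestic 405 nm) fiber-photometry recordings into z-scored traces and
    detects population synchronization events (SEs) with amplitude, onset and
    width-at-half-maximum metrics; detects per-cell calcium events and
    miniature synchronization events (mSEs) in brain-slice multi-ROI
    recordings and summarizes per-cell-per-hour rates across
    baseline/drug/wash epochs; quantifies membrane-voltage and firing-rate
    responses from patch-clamp recordings; and provides the accompanying exact
    nonparametric statistics (Wilcoxon signed-rank, Mann-Whitney U with mean
    rank difference, Holm-Sidak adjustment, repeated-measures ANOVA,
    leave-one-animal-out sensitivity analysis). A seeded synthetic-data module
    generates photometry, slice-network, membrane-voltage and spike-train
    datasets with ground truth so every pipeline stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
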