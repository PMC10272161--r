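Package: mozal
Title: Analysis of Mosquito Antennal Lobe Electrophysiology, Morphology and Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for intracellular recordings from
    projection neurons (PNs) and local neurons (LNs) of the mosquito antennal
    lobe. Detects spikes in membrane-potential traces and extracts four
    electrophysiological features (spike amplitude, half-width,
    after-hyperpolarization amplitude, isolated-spike fraction); types cells
    by unsupervised hierarchical clustering; quantifies odor-evoked firing
    rate changes with an exact Wilcoxon signed-rank responder criterion;
    decodes odor identity from population responses with a
    leave-one-trial-out nearest-centroid classifier and visualizes population
    dynamics as PCA trajectories; scores morphological similarity of SWC
    neuron skeletons with a normalized NBLAST-style metric after resampling
    and Strahler-based axon pruning; and relates two-choice olfactometer
    preference indices to PN population distances. Includes seeded synthetic
    generators for every data type so the full pipeline runs and is testable
    without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
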