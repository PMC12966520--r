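Package: calciscore
Title: Volume-Normalized Abdominal Artery Calcification Scoring from CTA
Version: 0.1.0
Authors@R: person("calciscore", "developers", role = c("aut", "cre"),
    email = "calciscore@example.org")
Description: Quantifies abdominal arterial calcification burden from
    contrast-enhanced CT angiography (CTA) label maps. Implements a
    vessel-tree shortening algorithm that standardizes side-artery length
    (iliac, mesenteric, renal) and truncates the aorta above the highest
    branch, threshold-based calcification segmentation baselines (per-case
    Dice-optimal search and a fixed clinical threshold), volume-normalized
    burden scores with cluster morphology per artery group, segmentation
    evaluation metrics (Dice, Jaccard, volumetric similarity, sensitivity,
    precision), and agreement statistics (Pearson, R-squared, regression,
    Bland-Altman, paired t-test). Ships a synthetic CTA phantom generator so
    the full pipeline is testable without clinical data, plus a command-line
    interface. Reads and writes NIfTI-1 volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
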