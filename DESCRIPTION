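Package: elsquant
Title: Quantification of Ectopic Lymphoid Structures in Salivary-Gland
    Immunofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for digital histopathology of
    sialadenitis: global-threshold pixel classification of multichannel
    immunofluorescence fields (DAPI plus T- and B-cell markers),
    pixel-exact conversion between binary masks and polygon regions
    (GeoJSON), detection of lymphocytic aggregates, nucleus counting,
    focus score and aggregate area fraction, and a T/B-cell segregation
    index. Includes a synthetic salivary-gland field simulator with
    exhaustive planted ground truth, a nonparametric statistical layer
    (exact Mann-Whitney and Wilcoxon signed-rank tests, Spearman
    correlation matrices with Benjamini-Hochberg adjustment, Grubbs
    outlier screening, delta-delta-Ct fold changes), and an
    orchestration layer that turns simulated or real cohorts into
    figure-ready tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
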