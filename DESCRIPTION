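Package: ribopause
Title: Codon-Resolved Ribosome Pausing Analysis for Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end ribosome-profiling (Ribo-seq) analysis pipeline for
    detecting codon-specific ribosome pausing, built around the statistics used
    to characterise AGA-codon stalling under arginine-tRNA deficiency: per-read-
    length A-site offset calibration from the start-codon metagene, per-codon
    observed/expected occupancy ratios, within-transcript pause z-scores with
    replicate intersection of pause-gene sets, pause-versus-expression
    correlation, and translational-efficiency (TE) analysis with A-site
    codon-filtered re-analysis and 5'TOP gene reporting. Includes a stochastic
    footprint simulator with a codon dwell-time model and implanted elongation
    stalls, providing ground truth for every downstream stage.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    Biostrings
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
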