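Package: waverate
Title: RNAPII Elongation Rates, Pausing Indices and Chromatin m6A Levels
    from Nascent RNA Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-gene RNA polymerase II elongation rates from
    DRB/4sU nascent-RNA release time courses by tracking the advancing
    transcription wave front with a two-segment changepoint detector,
    classifies genes into slow/medium/fast speed groups by three-quantile
    division, computes spike-in-corrected RNAPII occupancies and promoter
    pausing indices, quantifies m6A methylation levels on
    chromatin-associated RNA from IP/input read counts, and provides the
    rank tests and correlations used to relate elongation speed, pausing
    and RNA methylation. A synthetic-data generator with known ground
    truth (wave coverage, count tables, spike-in ledgers) makes the whole
    pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
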