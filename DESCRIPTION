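Package: vpdecode
Title: Metric-Space Decoding of Trial-Structured Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Victor-Purpura single- and two-unit spike-train distances with
    exact dynamic programming, leave-one-out metric-space classification of
    task epochs, permutation bias-corrected mutual information with
    consecutive-window significance, PETH-preserving spike shuffle controls,
    Fano factor diagnostics, paired-unit (q,k) information surfaces, and a
    deviation-from-prototype analysis linking single-trial temporal firing
    patterns to behavioral response times. Includes a seeded generator of
    task-structured synthetic sessions (trial-and-error problem solving with
    error, first-reward and repetition epochs) so the full pipeline runs
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
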