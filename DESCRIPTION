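Package: fibrilbreaks
Title: Segment-Level Conformational Heterogeneity in Amyloid Fibril Cryo-EM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of conformational heterogeneity ("structural breaks")
    along individual amyloid fibrils from cryo-EM helical reconstruction
    segment tables. Reads and writes per-segment class assignments (STAR
    particle tables or TSV), groups segments into fibrils ordered along the
    helical axis, summarises per-fibril conformational composition and run
    structure, and tests axial clustering of conformations against a
    within-fibril label-shuffling permutation null. Also provides helical
    lattice bookkeeping (twist, rise, pitch, crossover, extraction
    geometry), a two-state Markov chain simulator of fibril label sequences
    with classification noise for power and calibration studies, residue
    span annotation of ordered, disordered, and beta-strand regions of the
    FOR005 immunoglobulin light chain fibril protein, and the four-predictor
    per-residue aggregation consensus score.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
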