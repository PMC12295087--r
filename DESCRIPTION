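Package: ire1ridd
Title: IRE1 Activity Scoring and RIDD Target-Site Prediction from Transcript Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying IRE1 endoribonuclease signalling in bulk
    transcriptomes: prediction of regulated IRE1-dependent decay (RIDD) target
    sites in transcript isoforms via motif search and a stem-loop Boltzmann
    ensemble, isoform-switch testing and consequence classification (UTR gain,
    domain loss, coding to non-coding), quantile-based per-sample IRE1 activity
    scores with categorical association to condition, splicing-event by
    RIDD-recognizability association statistics (phi, chi-squared, Cramer's V,
    mutual information), FIMO-style position-weight-matrix scanning of promoters
    for XBP1s binding sites with exact p-values, and a fully seeded synthetic
    cohort generator with planted effects and a machine-readable truth table for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
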