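Package: dropscreen
Title: Pooled CRISPR Dropout Screen Analysis with Anchored Read Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled CRISPR/Cas9 loss-of-function (dropout) screens
    from raw amplicon reads to candidate genes. Reads are assigned to sgRNAs by
    anchored approximate matching of flanked cassette patterns (Hamming distance
    up to a mismatch budget, best match wins, ties discarded as ambiguous),
    counts are normalised to frequencies and summarised as per-sgRNA and
    per-gene log2 fold changes across a two-arm time course, essential and
    non-essential control genes are scored for quality control, and hits are
    called by per-timepoint depletion thresholds with control-arm exclusion and
    a minimum-sgRNA-support rule. A negative-binomial-like screen simulator with
    planted per-gene effects generates libraries, count matrices and FASTQ reads
    so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
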