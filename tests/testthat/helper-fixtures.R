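# Small deterministic fixtures shared across test files.

toy_library <- function(flank5 = "GACGAAACACCG", flank3 = "GTTTAAGAGCTA") {
  library_design(
    data.frame(
      sgrna_id = c("g1", "g2", "g3", "g4"),
      gene = c("A", "A", "B", "CTRL"),
      sequence = c("ACGTACGTACGTACGTACGT",
                   "TTTTCCCCGGGGAAAATTTT",
                   "GATCGATCGATCGATCGATC",
                   "CCCGGGAAATTTCCCGGGAA"),
      category = c("target", "target", "target", "essential_control")
    ),
    flank5 = flank5, flank3 = flank3
  )
}

write_toy_fastq <- function(reads, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(reads) > 0L) {
    writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n",
                      strrep("I", nchar(reads))), con)
  } else {
    writeLines(character(0), con)
  }
  path
}

# fold-change matrix with explicit per-contrast values for hit-calling tests
fc_matrix <- function(values, ids) {
  m <- matrix(values, nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, c("T1vsT0", "T2vsT0", "C1vsT0",
                                     "C2vsT0")))
  class(m) <- c("fold_change_table", class(m))
  m
}

qc_fixture_path <- function() {
  system.file("extdata", "qc_fixture_synthetic_gene_summary.tsv",
              package = "dropscreen", mustWork = TRUE)
}
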