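#!/usr/bin/env Rscript
# Stage 4: score the control genes and build the viability-exclusion list.
# Essential controls should deplete at least fourfold on average (mean
# log2FC <= -2 in the viability contrast); non-essential controls should
# stay above -1. Genes meeting the fourfold rule are putatively required
# for growth or division and are excluded from treatment-specific hit
# calling.

suppressPackageStartupMessages(library(dropscreen))

out <- "results/sim"
gs <- read_gene_summary(file.path(out, "gene_summary.tsv"))

qc <- control_qc(gs, "T0vsRef", depleted_threshold = -2,
                 stable_threshold = -1)
print(qc)
excluded <- viability_depleted_genes(gs, "T0vsRef", threshold = -2)
cat("viability-depleted target genes excluded from hit calling:",
    length(excluded), "\n")
if (length(excluded) > 0L) cat(" ", paste(excluded, collapse = ", "), "\n")

jsonlite::write_json(unclass(qc), file.path(out, "qc_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
writeLines(excluded, file.path(out, "viability_excluded.txt"))
cat("wrote qc_report.json and viability_excluded.txt\n")
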