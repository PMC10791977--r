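#!/usr/bin/env Rscript
# Stage 3: normalise the counts to reads-per-million (pseudocount 0.5) and
# compute per-sgRNA log2 fold changes for the screen's contrasts — the
# viability contrast T0 vs the uniform library expectation, and T1/T2
# (treatment arm) and C1/C2 (control arm) each vs T0 — then average within
# genes.

suppressPackageStartupMessages(library(dropscreen))

out <- "results/sim"
lib <- read_library_table(file.path(out, "library.tsv"))
counts <- read_count_matrix(file.path(out, "counts.tsv"))

freq <- normalize_counts(counts, pseudocount = 0.5, scale = 1e6)
fc <- log2_fold_changes(freq, default_contrasts(), scale = 1e6)
gs <- gene_mean_fc(fc, lib)

write_fold_changes(fc, lib, file.path(out, "fold_changes.tsv"))
write_gene_summary(gs, file.path(out, "gene_summary.tsv"))

cat("contrasts:", paste(colnames(fc), collapse = ", "), "\n")
cat(sprintf("gene-level T1vsT0 range: [%.2f, %.2f]\n",
            min(gs$T1vsT0), max(gs$T1vsT0)))
most <- gs[order(gs$T2vsT0), ][1:5, c("gene", "category", "n_sgrnas",
                                      "T1vsT0", "T2vsT0", "C2vsT0")]
cat("five most T2-depleted genes:\n")
print(most, row.names = FALSE)
cat("wrote fold_changes.tsv and gene_summary.tsv\n")
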