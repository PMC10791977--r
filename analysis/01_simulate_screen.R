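#!/usr/bin/env Rscript
# Stage 1: simulate a desk-scale two-arm dropout screen with raw reads.
#
# Generates a well-separated library (20 target genes + 45/47 control
# genes), plants treatment-sensitive hit genes, draws overdispersed counts
# for T0/T1/T2/C1/C2 at 5e4 reads per sample, and writes per-sample FASTQ
# with 0.1% substitution errors. Everything downstream (02-05) starts from
# these files, so the whole workflow is reproducible from this seed.

suppressPackageStartupMessages(library(dropscreen))

SEED <- 20260928L %% 1000000L
out <- "results/sim"
dir.create(file.path(out, "fastq"), showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_target_genes = 20L, fraction_hit_genes = 0.15,
                  depth_per_sample = 5e4, read_length = 75L,
                  substitution_error_rate = 0.001)
lib <- make_library(cfg, seed = SEED, well_separated = TRUE)
truth <- simulate_truth(lib, cfg, seed = SEED)
counts <- simulate_counts(lib, truth, cfg, seed = SEED)

write_library_table(lib, file.path(out, "library.tsv"))
write.table(truth$genes, file.path(out, "truth_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$sgrnas, file.path(out, "truth_sgrnas.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_count_matrix(counts, lib, file.path(out, "true_counts.tsv"))

for (s in colnames(counts)) {
  simulate_fastq(counts[, s], lib, cfg, seed = SEED + match(s, colnames(counts)),
                 out_path = file.path(out, "fastq", paste0(s, ".fq.gz")))
}

rep <- validate_library(lib, min_hamming = TRUE)
print(rep)
n_hits <- sum(truth$genes$class == "tcell_hit")
cat("planted", n_hits, "treatment-sensitive hit genes:",
    paste(truth$genes$gene[truth$genes$class == "tcell_hit"],
          collapse = ", "), "\n")
cat("wrote library, truth, counts and", ncol(counts), "FASTQ files under",
    out, "\n")
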