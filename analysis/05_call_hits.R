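#!/usr/bin/env Rscript
# Stage 5: nominate candidate genes. An sgRNA scores when it is depleted in
# both treatment rounds (T1 < -1, T2 < -2, strict) and not depleted in the
# engager-free control arm (C1 < -1 and C2 < -2); a gene is a hit when at
# least two of its sgRNAs score and it is not on the viability-exclusion
# list. The planted truth from stage 1 grades the calls.

suppressPackageStartupMessages(library(dropscreen))

out <- "results/sim"
lib <- read_library_table(file.path(out, "library.tsv"))
fc_tab <- read.delim(file.path(out, "fold_changes.tsv"),
                     check.names = FALSE)
fc <- as.matrix(fc_tab[, setdiff(names(fc_tab), c("sgrna_id", "gene"))])
rownames(fc) <- fc_tab$sgrna_id
class(fc) <- c("fold_change_table", class(fc))
excluded <- readLines(file.path(out, "viability_excluded.txt"))

flags <- flag_sgrnas(fc, t1_thresh = -1, t2_thresh = -2,
                     c1_thresh = -1, c2_thresh = -2, combine = "both")
hits <- call_hits(flags, lib, excluded_genes = excluded, min_support = 2L)
write_hit_table(hits, file.path(out, "hits.tsv"))

cat("hits called:", sum(hits$hit), "\n")
print(hits[hits$hit, c("gene", "n_eligible", "supporting_sgrnas")],
      row.names = FALSE)

truth_genes <- read.delim(file.path(out, "truth_genes.tsv"))
truth_sgrnas <- read.delim(file.path(out, "truth_sgrnas.tsv"))
truth <- structure(list(genes = truth_genes, sgrnas = truth_sgrnas),
                   class = "simulation_truth")
rec <- evaluate_recovery(hits, truth)
cat(sprintf("recovery vs planted truth: tp %d fp %d fn %d (precision %.2f, recall %.2f)\n",
            rec$tp, rec$fp, rec$fn, rec$precision, rec$recall))
cat("wrote hits.tsv\n")
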