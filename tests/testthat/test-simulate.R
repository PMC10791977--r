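small_cfg <- function(...) {
  sim_config(n_target_genes = 10L, n_essential_controls = 5L,
             n_nonessential_controls = 5L, ...)
}

test_that("simulated libraries have the configured shape, reproducibly", {
  cfg <- sim_config(n_target_genes = 10L)
  lib1 <- make_library(cfg, seed = 3)
  lib2 <- make_library(cfg, seed = 3)
  expect_identical(as.data.frame(lib1), as.data.frame(lib2))

  rep <- validate_library(lib1)
  expect_equal(unname(rep$genes_per_category),
               c(10L, 45L, 47L))
  expect_true(rep$per_gene_range["min"] >= 3L)
  expect_true(rep$per_gene_range["max"] <= 12L)
  n_target <- rep$category_counts[["target"]]
  expect_true(n_target >= 30L && n_target <= 120L)
  expect_true(all(nchar(lib1$sequence) == 20L))

  lib3 <- make_library(cfg, seed = 4)
  expect_false(identical(lib1$sequence, lib3$sequence))
  expect_equal(validate_library(lib3)$genes_per_category,
               rep$genes_per_category)
})

min_pairwise_hamming_test <- function(seqs) {
  # independent quadratic check in plain R
  best <- nchar(seqs[1L])
  chars <- strsplit(seqs, "")
  for (i in seq_along(chars)) {
    for (j in seq_len(i - 1L)) {
      best <- min(best, sum(chars[[i]] != chars[[j]]))
    }
  }
  best
}

test_that("well-separated libraries satisfy the distance guarantee", {
  cfg <- small_cfg()
  lib <- make_library(cfg, seed = 9, well_separated = TRUE)
  expect_true(min_pairwise_hamming_test(lib$sequence) >= 5L)
})

test_that("planted truth respects class fractions and effect distributions", {
  cfg <- small_cfg(fraction_hit_genes = 0)
  lib <- make_library(cfg, seed = 2)
  tr <- simulate_truth(lib, cfg, seed = 2)
  targets <- tr$genes[tr$genes$category == "target", ]
  expect_true(all(targets$class == "neutral"))
  expect_true(all(targets$hit_effect_per_round == 0))
  ess <- tr$genes[tr$genes$category == "essential_control", ]
  expect_true(all(ess$class == "essential_like"))
  expect_true(all(ess$viability_effect != 0))

  cfg1 <- small_cfg(fraction_hit_genes = 1,
                    hit_effect_per_round = c(mean = -3, sd = 0))
  tr1 <- simulate_truth(lib, cfg1, seed = 2)
  t1 <- tr1$genes[tr1$genes$category == "target", ]
  expect_true(all(t1$class == "tcell_hit"))
  expect_true(all(t1$hit_effect_per_round == -3))

  # law of large numbers on the viability effect distribution
  cfg_big <- sim_config(n_target_genes = 1L, n_essential_controls = 1000L,
                        n_nonessential_controls = 1L)
  lib_big <- make_library(cfg_big, seed = 6)
  tr_big <- simulate_truth(lib_big, cfg_big, seed = 6)
  drawn <- tr_big$genes$viability_effect[
    tr_big$genes$category == "essential_control"]
  expect_equal(mean(drawn), -3, tolerance = 0.05 / 3)
  expect_equal(sd(drawn), 0.5, tolerance = 0.1)

  # per-sgRNA offsets only modulate genes with a non-zero effect
  neutral_sg <- tr$sgrnas$gene %in% targets$gene
  expect_true(all(tr$sgrnas$hit_offset[neutral_sg] == 0))
})

test_that("simulated counts have the screen's arm structure", {
  # sparse hits, so that depleting them barely renormalises the pool and
  # estimated fold changes converge on the planted effects
  cfg <- sim_config(n_target_genes = 100L, fraction_hit_genes = 0.05,
                    hit_effect_per_round = c(mean = -1, sd = 0),
                    sgrna_scatter_sd = 0, nb_dispersion = 0,
                    depth_per_sample = 1e6)
  lib <- make_library(cfg, seed = 8)
  tr <- simulate_truth(lib, cfg, seed = 8)
  cm <- simulate_counts(lib, tr, cfg, seed = 8)
  expect_identical(colnames(cm), c("T0", "T1", "T2", "C1", "C2"))
  expect_equal(unname(colSums(cm)), rep(1e6, 5L))
  expect_identical(cm, simulate_counts(lib, tr, cfg, seed = 8))

  fc <- log2_fold_changes(normalize_counts(cm), default_contrasts())
  gs <- gene_mean_fc(fc, lib)
  hit_genes <- tr$genes$gene[tr$genes$class == "tcell_hit"]
  neutral_targets <- tr$genes$gene[tr$genes$class == "neutral" &
                                     tr$genes$category == "target"]
  # per-round effect -1 compounds to -2 by round two, treatment arm only
  expect_equal(mean(gs$T1vsT0[gs$gene %in% hit_genes]), -1,
               tolerance = 0.1)
  expect_equal(mean(gs$T2vsT0[gs$gene %in% hit_genes]), -2,
               tolerance = 0.1)
  expect_equal(mean(gs$C1vsT0[gs$gene %in% hit_genes]), 0,
               tolerance = 0.1)
  expect_equal(mean(gs$C2vsT0[gs$gene %in% hit_genes]), 0,
               tolerance = 0.1)
  # null model: neutral genes drift nowhere
  expect_equal(mean(gs$T2vsT0[gs$gene %in% neutral_targets]), 0,
               tolerance = 0.1)
})

test_that("simulated FASTQ is deterministic and structurally correct", {
  cfg <- small_cfg(substitution_error_rate = 0)
  lib <- make_library(cfg, seed = 13, well_separated = TRUE)
  counts <- setNames(rep(0L, nrow(lib)), lib$sgrna_id)
  counts[1:5] <- c(10L, 0L, 3L, 7L, 1L)

  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  simulate_fastq(counts, lib, cfg, seed = 14, out_path = f1)
  simulate_fastq(counts, lib, cfg, seed = 14, out_path = f2)
  expect_identical(readLines(f1), readLines(f2))

  lines <- readLines(f1)
  expect_equal(length(lines), 4L * sum(counts))
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  expect_true(all(nchar(seqs) == cfg$read_length))

  # round trip at error rate zero recovers the exact counts
  res <- count_sample(f1, build_query_patterns(lib))
  expect_identical(res$counts, counts)
  expect_equal(res$stats$unassigned + res$stats$ambiguous, 0L)

  # empty counts give an empty file
  f0 <- withr::local_tempfile(fileext = ".fq")
  simulate_fastq(setNames(rep(0L, nrow(lib)), lib$sgrna_id), lib, cfg,
                 seed = 14, out_path = f0)
  expect_equal(length(readLines(f0)), 0L)

  # reads must be able to carry the cassette
  cfg_short <- small_cfg(read_length = 30L)
  expect_error(simulate_fastq(counts, lib, cfg_short, 14,
                              withr::local_tempfile(fileext = ".fq")),
               "read_length")
})

test_that("substitution errors appear at roughly the configured rate", {
  cfg <- small_cfg(substitution_error_rate = 0.01, read_length = 60L)
  lib <- make_library(cfg, seed = 15, well_separated = TRUE)
  counts <- setNames(rep(0L, nrow(lib)), lib$sgrna_id)
  counts[1:10] <- 200L
  fq <- withr::local_tempfile(fileext = ".fq")
  simulate_fastq(counts, lib, cfg, seed = 16, out_path = fq)
  res <- count_sample(fq, build_query_patterns(lib))
  st <- res$stats
  expect_equal(st$total_reads, 2000L)
  expect_equal(st$assigned + st$ambiguous + st$unassigned, 2000L)
  # cassette is 44 nt at 1% per-base error: most reads carry <= 2 errors
  expect_true(st$assigned / st$total_reads > 0.95)
  expect_true(sum(st$mismatch_histogram[c("1", "2")]) > 0L)
})
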