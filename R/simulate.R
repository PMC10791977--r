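#' Configuration for a synthetic dropout screen
#'
#' Collects every knob of the generative model with defaults shaped like the
#' screen being emulated: a library with 3-12 sgRNAs per gene, 45 essential
#' and 47 non-essential control genes, lognormal baseline abundances,
#' planted per-gene viability and per-round treatment effects with per-sgRNA
#' scatter, gamma-multinomial (negative-binomial-like) sampling at fixed
#' depth, and cassette-structured reads with substitution errors.
#'
#' Effects are on the log2 scale. Viability effects act in every sample from
#' T0 on; treatment effects act only in the treatment arm and accumulate
#' additively in log2 across the two rounds.
#'
#' @param n_target_genes Number of non-control genes.
#' @param sgrnas_per_gene_range Integer pair; per-gene sgRNA counts are drawn
#'   uniformly from this range (default 3-12, controls included).
#' @param n_essential_controls,n_nonessential_controls Control gene counts
#'   (defaults 45 and 47).
#' @param fraction_hit_genes Fraction of target genes planted as
#'   treatment-sensitive hits (default 0.05).
#' @param fraction_viability_targets Fraction of target genes planted as
#'   essential-like (depleted from T0 on; default 0).
#' @param viability_effect Mean and sd of per-gene log2 viability effects for
#'   essential-class genes (default -3, 0.5).
#' @param hit_effect_per_round Mean and sd of per-gene log2 treatment effects
#'   applied per round (default -1.5, 0.3).
#' @param sgrna_scatter_sd Per-sgRNA deviation (log2) around its gene effect
#'   (default 0.25).
#' @param baseline_log_abundance_sd sdlog of the lognormal baseline
#'   abundances (default 1.0).
#' @param nb_dispersion Gamma dispersion of abundances before multinomial
#'   sampling; 0 gives a pure multinomial (default 0.05).
#' @param depth_per_sample Sequencing depth per sample (default 1e6).
#' @param read_length Simulated read length in nt (default 75).
#' @param substitution_error_rate Per-base substitution error rate in
#'   simulated reads (default 0.001).
#' @param protospacer_length Protospacer length in nt (default 20).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_target_genes = 100L,
                       sgrnas_per_gene_range = c(3L, 12L),
                       n_essential_controls = 45L,
                       n_nonessential_controls = 47L,
                       fraction_hit_genes = 0.05,
                       fraction_viability_targets = 0,
                       viability_effect = c(mean = -3, sd = 0.5),
                       hit_effect_per_round = c(mean = -1.5, sd = 0.3),
                       sgrna_scatter_sd = 0.25,
                       baseline_log_abundance_sd = 1.0,
                       nb_dispersion = 0.05,
                       depth_per_sample = 1e6,
                       read_length = 75L,
                       substitution_error_rate = 0.001,
                       protospacer_length = 20L) {
  stopifnot(n_target_genes >= 1L,
            length(sgrnas_per_gene_range) == 2L,
            sgrnas_per_gene_range[1L] >= 1L,
            sgrnas_per_gene_range[1L] <= sgrnas_per_gene_range[2L],
            fraction_hit_genes >= 0, fraction_hit_genes <= 1,
            fraction_viability_targets >= 0,
            fraction_viability_targets <= 1,
            nb_dispersion >= 0, depth_per_sample >= 1,
            substitution_error_rate >= 0, substitution_error_rate < 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

new_rng_seed <- function(seed, stream) {
  # deterministic per-operation sub-seed, kept inside 32-bit integer range
  as.integer((as.numeric(seed) * 7L + stream * 104729) %% 2147483647)
}

random_dna <- function(n_strings, lengths) {
  if (n_strings == 0L) return(character(0))
  lengths <- rep_len(lengths, n_strings)
  pool <- sample(DNA_ALPHABET, sum(lengths), replace = TRUE)
  big <- paste(pool, collapse = "")
  ends <- cumsum(lengths)
  substring(big, ends - lengths + 1L, ends)
}

#' Generate a random sgRNA library
#'
#' Random unique protospacers over A/C/G/T with per-gene sgRNA counts drawn
#' uniformly from the configured range; control genes are labelled. With
#' `well_separated = TRUE` the library is regenerated (bounded retries)
#' until the minimum pairwise Hamming distance among protospacers — and
#' hence among cassettes, which share the fixed flanks — is at least
#' `min_separation`, guaranteeing unambiguous assignment for error-free
#' reads at the default mismatch budget.
#'
#' @param config A [sim_config].
#' @param seed Integer seed; same seed, same library.
#' @param well_separated Enforce a minimum pairwise Hamming distance.
#' @param min_separation Minimum distance when `well_separated` (default 5 =
#'   2 x max_mm + 1 at the default budget of 2).
#' @param max_tries Regeneration attempts before failing.
#' @return A [library_design].
#' @export
make_library <- function(config, seed, well_separated = FALSE,
                         min_separation = 5L, max_tries = 20L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(new_rng_seed(seed, 1L))
  genes <- c(
    sprintf("GENE%04d", seq_len(config$n_target_genes)),
    sprintf("ESS%02d", seq_len(config$n_essential_controls)),
    sprintf("NON%02d", seq_len(config$n_nonessential_controls))
  )
  category <- rep(SGRNA_CATEGORIES,
                  c(config$n_target_genes, config$n_essential_controls,
                    config$n_nonessential_controls))
  rng <- config$sgrnas_per_gene_range
  n_per_gene <- sample(seq(rng[1L], rng[2L]), length(genes), replace = TRUE)
  gene_col <- rep(genes, n_per_gene)
  cat_col <- rep(category, n_per_gene)
  id_col <- paste0(gene_col, "_sg",
                   unlist(lapply(n_per_gene, seq_len), use.names = FALSE))
  n <- length(id_col)
  for (try in seq_len(max_tries)) {
    seqs <- random_dna(n, config$protospacer_length)
    if (anyDuplicated(seqs)) next
    if (well_separated && n >= 2L && min_hamming_cpp(seqs) < min_separation) {
      next
    }
    return(library_design(
      data.frame(sgrna_id = id_col, gene = gene_col, sequence = seqs,
                 category = cat_col, stringsAsFactors = FALSE)
    ))
  }
  stop("could not generate a library satisfying the separation constraint ",
       "after ", max_tries, " attempts", call. = FALSE)
}

#' Plant per-gene effects for a synthetic screen
#'
#' Essential-control genes (and a configured fraction of target genes) are
#' `essential_like` with log2 viability effects drawn from the configured
#' distribution; a configured fraction of target genes are `tcell_hit` with
#' per-round treatment effects; all other genes are `neutral`. Per-sgRNA
#' offsets around the gene effect are drawn once and reused across all
#' timepoints. Treatment effects never act in the control arm.
#'
#' @param lib A [library_design].
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A list of class `simulation_truth` with data frames `genes`
#'   (`gene`, `category`, `class`, `viability_effect`,
#'   `hit_effect_per_round`) and `sgrnas` (`sgrna_id`, `gene`,
#'   `viability_offset`, `hit_offset`).
#' @export
simulate_truth <- function(lib, config, seed) {
  stopifnot(inherits(lib, "library_design"), inherits(config, "sim_config"))
  set.seed(new_rng_seed(seed, 2L))
  gene_cat <- unique(as.data.frame(lib)[, c("gene", "category")])
  n_genes <- nrow(gene_cat)
  class_ <- rep("neutral", n_genes)
  viab <- numeric(n_genes)
  hit <- numeric(n_genes)

  ess <- gene_cat$category == "essential_control"
  class_[ess] <- "essential_like"
  viab[ess] <- rnorm(sum(ess), config$viability_effect[["mean"]],
                     config$viability_effect[["sd"]])

  target_idx <- which(gene_cat$category == "target")
  n_viab_targets <- round(config$fraction_viability_targets *
                            length(target_idx))
  n_hit_targets <- round(config$fraction_hit_genes * length(target_idx))
  n_pick <- min(n_viab_targets + n_hit_targets, length(target_idx))
  picked <- target_idx[sample.int(length(target_idx), n_pick)]
  viab_targets <- picked[seq_len(n_viab_targets)]
  hit_targets <- setdiff(picked, viab_targets)
  class_[viab_targets] <- "essential_like"
  viab[viab_targets] <- rnorm(length(viab_targets),
                              config$viability_effect[["mean"]],
                              config$viability_effect[["sd"]])
  class_[hit_targets] <- "tcell_hit"
  hit[hit_targets] <- rnorm(length(hit_targets),
                            config$hit_effect_per_round[["mean"]],
                            config$hit_effect_per_round[["sd"]])

  genes <- data.frame(gene = gene_cat$gene, category = gene_cat$category,
                      class = class_, viability_effect = viab,
                      hit_effect_per_round = hit, stringsAsFactors = FALSE)
  sgrnas <- data.frame(
    sgrna_id = lib$sgrna_id, gene = lib$gene,
    viability_offset = rnorm(nrow(lib), 0, config$sgrna_scatter_sd),
    hit_offset = rnorm(nrow(lib), 0, config$sgrna_scatter_sd),
    stringsAsFactors = FALSE
  )
  # offsets only modulate non-zero gene effects
  g <- match(sgrnas$gene, genes$gene)
  sgrnas$viability_offset[genes$viability_effect[g] == 0] <- 0
  sgrnas$hit_offset[genes$hit_effect_per_round[g] == 0] <- 0
  out <- list(genes = genes, sgrnas = sgrnas)
  class(out) <- "simulation_truth"
  out
}

#' Simulate a screen count matrix over T0, T1, T2, C1 and C2
#'
#' Latent per-sgRNA abundance is a lognormal baseline times
#' `2^(viability effect + offset)` in every sample, additionally times
#' `2^(k * hit effect + offset)` after treatment round k (k = 1, 2) in the
#' treatment arm only. Counts per sample are multinomial at the configured
#' depth; with `nb_dispersion > 0` the abundances are first perturbed by
#' independent gamma factors with unit mean and variance `nb_dispersion`,
#' giving negative-binomial-like overdispersion while preserving fixed
#' sequencing depth.
#'
#' @param lib A [library_design].
#' @param truth A `simulation_truth` from [simulate_truth()].
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A `count_matrix` with columns `T0`, `T1`, `T2`, `C1`, `C2`.
#' @export
simulate_counts <- function(lib, truth, config, seed) {
  stopifnot(inherits(lib, "library_design"),
            inherits(truth, "simulation_truth"),
            inherits(config, "sim_config"),
            config$depth_per_sample >= nrow(lib))
  set.seed(new_rng_seed(seed, 3L))
  n <- nrow(lib)
  g <- match(lib$gene, truth$genes$gene)
  s <- match(lib$sgrna_id, truth$sgrnas$sgrna_id)
  baseline <- rlnorm(n, meanlog = 0,
                     sdlog = config$baseline_log_abundance_sd)
  viab_mult <- 2^(truth$genes$viability_effect[g] +
                    truth$sgrnas$viability_offset[s])
  hit_log2 <- truth$genes$hit_effect_per_round[g]
  hit_off <- truth$sgrnas$hit_offset[s]
  treat_mult <- function(k) {
    m <- rep(1, n)
    active <- hit_log2 != 0
    m[active] <- 2^(k * hit_log2[active] + hit_off[active])
    m
  }
  abund <- list(
    T0 = baseline * viab_mult,
    T1 = baseline * viab_mult * treat_mult(1),
    T2 = baseline * viab_mult * treat_mult(2),
    C1 = baseline * viab_mult,
    C2 = baseline * viab_mult
  )
  depth <- as.integer(config$depth_per_sample)
  draw <- function(a) {
    if (config$nb_dispersion > 0) {
      shape <- 1 / config$nb_dispersion
      a <- a * rgamma(n, shape = shape, rate = shape)
    }
    as.integer(rmultinom(1L, size = depth, prob = a / sum(a)))
  }
  cols <- lapply(abund, function(a) setNames(draw(a), lib$sgrna_id))
  build_count_matrix(cols)
}

#' Simulate FASTQ reads for one sample
#'
#' Emits exactly `sum(counts)` reads in randomised order. Each read embeds
#' the sgRNA cassette (`flank5 + protospacer + flank3`) at a random offset
#' between random flanking sequence, trimmed to `read_length`, with
#' independent per-base substitution errors at the configured rate and a
#' constant quality string. Byte-identical output for identical seeds.
#'
#' @param counts Named integer vector of reads per sgRNA.
#' @param lib A [library_design] covering `names(counts)`.
#' @param config A [sim_config]; `read_length` must be at least the longest
#'   cassette.
#' @param seed Integer seed.
#' @param out_path Output path; a `.gz` suffix gzip-compresses.
#' @return `out_path`, invisibly.
#' @export
simulate_fastq <- function(counts, lib, config, seed, out_path) {
  stopifnot(inherits(lib, "library_design"), inherits(config, "sim_config"))
  if (is.null(names(counts)) ||
      !all(names(counts) %in% lib$sgrna_id)) {
    stop("counts must be named by library sgrna_id", call. = FALSE)
  }
  patterns <- build_query_patterns(lib)
  cassette_of <- setNames(patterns$cassette, patterns$sgrna_id)
  rl <- as.integer(config$read_length)
  max_cl <- max(nchar(patterns$cassette))
  if (rl < max_cl) {
    stop("read_length (", rl, ") shorter than longest cassette (", max_cl,
         ")", call. = FALSE)
  }
  set.seed(new_rng_seed(seed, 4L))
  total <- sum(counts)
  con <- if (grepl("\\.gz$", out_path)) gzfile(out_path, "wb") else
    file(out_path, "wb")
  on.exit(close(con))
  if (total == 0L) {
    writeLines(character(0), con)
    return(invisible(out_path))
  }
  ids <- rep(names(counts), counts)
  ids <- ids[sample.int(total)]
  cassettes <- unname(cassette_of[ids])
  cl <- nchar(cassettes)
  pre_len <- floor(runif(total) * (rl - cl + 1L))
  suf_len <- rl - cl - pre_len
  reads <- paste0(random_dna(total, pre_len), cassettes,
                  random_dna(total, suf_len))
  if (config$substitution_error_rate > 0) {
    reads <- add_substitution_errors(reads, rl,
                                     config$substitution_error_rate)
  }
  qual <- strrep("I", rl)
  rec <- paste0("@read", seq_len(total), "_", ids, "\n", reads, "\n+\n",
                qual)
  writeLines(rec, con)
  invisible(out_path)
}

add_substitution_errors <- function(reads, read_length, rate) {
  n_pos <- length(reads) * read_length
  err <- which(runif(n_pos) < rate)
  if (length(err) == 0L) return(reads)
  read_idx <- (err - 1L) %/% read_length + 1L
  base_idx <- (err - 1L) %% read_length + 1L
  for (k in seq_along(err)) {
    r <- read_idx[k]; p <- base_idx[k]
    old <- substr(reads[r], p, p)
    new <- sample(setdiff(DNA_ALPHABET, old), 1L)
    substr(reads[r], p, p) <- new
  }
  reads
}

#' Simulate a complete screen
#'
#' Convenience wrapper: library, planted truth and count matrix from one
#' config and seed.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @param well_separated Passed to [make_library()].
#' @return A list with `lib`, `truth` and `counts`.
#' @export
simulate_screen <- function(config, seed, well_separated = FALSE) {
  lib <- make_library(config, seed, well_separated = well_separated)
  truth <- simulate_truth(lib, config, seed)
  counts <- simulate_counts(lib, truth, config, seed)
  list(lib = lib, truth = truth, counts = counts)
}
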