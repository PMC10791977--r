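#' Assemble a pipeline run configuration
#'
#' Inputs may be given either as a sample manifest mapping the five screen
#' timepoints to FASTQ files (counted with the anchored matcher) or as a
#' precomputed count matrix (object or TSV path). Thresholds default to the
#' screen's published rules: treatment depletion T1 < -1 and T2 < -2,
#' control-arm exclusion C1 < -1 and C2 < -2 (conjunction), viability
#' exclusion at mean log2FC <= -2, and at least two eligible sgRNAs per hit.
#'
#' @param library A [library_design] or path to a library TSV.
#' @param counts A `count_matrix`, a path to a counts TSV, or `NULL` when
#'   `fastq_manifest` is given.
#' @param fastq_manifest Named character vector of FASTQ paths, names being
#'   sample labels (must include `T0`, `T1`, `T2`, `C1`, `C2` unless
#'   `reduced_design = TRUE`).
#' @param contrasts List of [contrast_spec]; default [default_contrasts()].
#' @param viability_contrast Contrast used for QC and viability exclusion.
#' @param t1_thresh,t2_thresh,c1_thresh,c2_thresh,combine Hit-calling
#'   thresholds, see [flag_sgrnas()].
#' @param viability_threshold Inclusive bound for viability exclusion.
#' @param stable_threshold QC stability bound for non-essential controls.
#' @param min_support Minimum eligible sgRNAs per hit gene.
#' @param max_mm,revcomp Matcher settings, see [count_sample()].
#' @param pseudocount,scale Normalisation settings, see [normalize_counts()].
#' @param reduced_design Allow a manifest without the full five timepoints.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(library, counts = NULL, fastq_manifest = NULL,
                       contrasts = default_contrasts(),
                       viability_contrast = "T0vsRef",
                       t1_thresh = -1, t2_thresh = -2,
                       c1_thresh = -1, c2_thresh = -2,
                       combine = "both",
                       viability_threshold = -2, stable_threshold = -1,
                       min_support = 2L, max_mm = 2L, revcomp = FALSE,
                       pseudocount = 0.5, scale = 1e6,
                       reduced_design = FALSE, out_dir = "dropscreen_run") {
  if (is.null(counts) && is.null(fastq_manifest)) {
    stop("either counts or fastq_manifest must be provided", call. = FALSE)
  }
  if (!is.null(fastq_manifest) && !isTRUE(reduced_design)) {
    need <- c("T0", "T1", "T2", "C1", "C2")
    missing_tp <- setdiff(need, names(fastq_manifest))
    if (length(missing_tp) > 0L) {
      stop("fastq_manifest is missing timepoint(s): ",
           paste(missing_tp, collapse = ", "),
           " (set reduced_design = TRUE for partial designs)",
           call. = FALSE)
    }
  }
  cfg <- list(library = library, counts = counts,
              fastq_manifest = fastq_manifest, contrasts = contrasts,
              viability_contrast = viability_contrast,
              t1_thresh = t1_thresh, t2_thresh = t2_thresh,
              c1_thresh = c1_thresh, c2_thresh = c2_thresh,
              combine = combine, viability_threshold = viability_threshold,
              stable_threshold = stable_threshold,
              min_support = as.integer(min_support),
              max_mm = as.integer(max_mm), revcomp = revcomp,
              pseudocount = pseudocount, scale = scale,
              reduced_design = reduced_design, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full screen analysis
#'
#' Orchestrates count (if starting from FASTQ), normalise, fold change,
#' gene summary, control QC, viability exclusion and hit calling, writing
#' every artifact plus run metadata and a log into `config$out_dir`.
#' Identical configuration and inputs produce identical outputs.
#'
#' @param config A [run_config].
#' @param quiet Suppress console logging.
#' @return Invisibly, a list with all in-memory results (`counts`, `freq`,
#'   `fc`, `gene_summary`, `qc`, `excluded_genes`, `hits`, `paths`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }

  lib <- config$library
  if (is.character(lib)) lib <- read_library_table(lib)
  stopifnot(inherits(lib, "library_design"))
  say("library: ", nrow(lib), " sgRNAs, ", length(unique(lib$gene)),
      " genes")

  stats_per_sample <- NULL
  counts <- config$counts
  if (is.null(counts)) {
    patterns <- build_query_patterns(lib)
    vecs <- list()
    stats_per_sample <- list()
    for (s in names(config$fastq_manifest)) {
      res <- count_sample(config$fastq_manifest[[s]], patterns,
                          max_mm = config$max_mm, revcomp = config$revcomp)
      vecs[[s]] <- res$counts
      stats_per_sample[[s]] <- res$stats
      say("counted ", s, ": ", res$stats$assigned, "/",
          res$stats$total_reads, " reads assigned, ",
          res$stats$ambiguous, " ambiguous")
    }
    counts <- build_count_matrix(vecs)
  } else if (is.character(counts)) {
    counts <- read_count_matrix(counts)
  }
  if (!all(rownames(counts) %in% lib$sgrna_id)) {
    stop("count matrix contains sgRNAs absent from the library",
         call. = FALSE)
  }

  freq <- normalize_counts(counts, pseudocount = config$pseudocount,
                           scale = config$scale)
  fc <- log2_fold_changes(freq, config$contrasts, scale = config$scale)
  gs <- gene_mean_fc(fc, lib)
  qc <- control_qc(gs, config$viability_contrast,
                   depleted_threshold = config$viability_threshold,
                   stable_threshold = config$stable_threshold)
  say("QC: essential depleted ", qc$essential_depleted, "/",
      qc$essential_total, "; non-essential stable ",
      qc$nonessential_stable, "/", qc$nonessential_total)
  excluded <- viability_depleted_genes(gs, config$viability_contrast,
                                       threshold = config$viability_threshold)
  say("viability-depleted genes excluded from hit calling: ",
      length(excluded))
  flags <- flag_sgrnas(fc, t1_thresh = config$t1_thresh,
                       t2_thresh = config$t2_thresh,
                       c1_thresh = config$c1_thresh,
                       c2_thresh = config$c2_thresh,
                       combine = config$combine)
  hits <- call_hits(flags, lib, excluded_genes = excluded,
                    min_support = config$min_support)
  say("hits called: ", sum(hits$hit))

  paths <- list(
    counts = file.path(config$out_dir, "counts.tsv"),
    fold_changes = file.path(config$out_dir, "fold_changes.tsv"),
    gene_summary = file.path(config$out_dir, "gene_summary.tsv"),
    qc = file.path(config$out_dir, "qc_report.json"),
    excluded = file.path(config$out_dir, "viability_excluded.txt"),
    hits = file.path(config$out_dir, "hits.tsv"),
    metadata = file.path(config$out_dir, "run_metadata.json"),
    log = log_path
  )
  write_count_matrix(counts, lib, paths$counts)
  write_fold_changes(fc, lib, paths$fold_changes)
  write_gene_summary(gs, paths$gene_summary)
  jsonlite::write_json(unclass(qc), paths$qc, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(excluded, paths$excluded)
  write_hit_table(hits, paths$hits)
  metadata <- list(
    package_version = as.character(utils::packageVersion("dropscreen")),
    thresholds = list(t1 = config$t1_thresh, t2 = config$t2_thresh,
                      c1 = config$c1_thresh, c2 = config$c2_thresh,
                      viability = config$viability_threshold,
                      stable = config$stable_threshold,
                      combine = config$combine,
                      min_support = config$min_support),
    matcher = list(max_mm = config$max_mm, revcomp = config$revcomp),
    normalization = list(pseudocount = config$pseudocount,
                         scale = config$scale),
    contrasts = lapply(config$contrasts, unclass),
    assignment_stats = lapply(stats_per_sample, function(s) {
      s$mismatch_histogram <- as.list(s$mismatch_histogram)
      unclass(s)
    })
  )
  jsonlite::write_json(metadata, paths$metadata, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)

  invisible(list(counts = counts, freq = freq, fc = fc, gene_summary = gs,
                 qc = qc, excluded_genes = excluded, hits = hits,
                 stats = stats_per_sample, paths = paths))
}
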