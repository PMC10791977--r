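#' Flag sgRNAs by treatment-arm and control-arm depletion
#'
#' An sgRNA passes the treatment criterion when it is depleted in *both*
#' consecutive treatment rounds (strict inequalities: T1 < `t1_thresh` and
#' T2 < `t2_thresh`). It is flagged as a control-arm dropout when it is
#' depleted in the arm without the engager, which removes guides against
#' genes acting through treatment-unspecific T cell effects; `combine`
#' decides whether both control timepoints must be depleted (default) or
#' either one suffices. An sgRNA is eligible to support a hit when it passes
#' the treatment criterion and is not a control-arm dropout.
#'
#' @param fc A `fold_change_table` containing the four contrasts.
#' @param t1_thresh,t2_thresh Strict depletion bounds for treatment rounds 1
#'   and 2 (defaults -1 and -2).
#' @param c1_thresh,c2_thresh Strict depletion bounds for control rounds 1
#'   and 2 (defaults -1 and -2).
#' @param combine `"both"` (conjunction, default) or `"either"` for the
#'   control-arm rule.
#' @param contrast_names Named character vector resolving the four roles to
#'   column names of `fc`.
#' @return A data frame of class `sgrna_flags`: `sgrna_id`,
#'   `treatment_pass`, `control_depleted`, `eligible`.
#' @export
flag_sgrnas <- function(fc, t1_thresh = -1, t2_thresh = -2,
                        c1_thresh = -1, c2_thresh = -2,
                        combine = c("both", "either"),
                        contrast_names = c(t1 = "T1vsT0", t2 = "T2vsT0",
                                           c1 = "C1vsT0", c2 = "C2vsT0")) {
  combine <- match.arg(combine)
  stopifnot(is.matrix(fc))
  missing_ct <- setdiff(unname(contrast_names), colnames(fc))
  if (length(missing_ct) > 0L) {
    stop("fold-change table is missing contrast(s): ",
         paste(missing_ct, collapse = ", "), call. = FALSE)
  }
  t1 <- fc[, contrast_names[["t1"]]]
  t2 <- fc[, contrast_names[["t2"]]]
  c1 <- fc[, contrast_names[["c1"]]]
  c2 <- fc[, contrast_names[["c2"]]]
  treatment_pass <- t1 < t1_thresh & t2 < t2_thresh
  control_depleted <- if (combine == "both") {
    c1 < c1_thresh & c2 < c2_thresh
  } else {
    c1 < c1_thresh | c2 < c2_thresh
  }
  out <- data.frame(
    sgrna_id = rownames(fc),
    treatment_pass = unname(treatment_pass),
    control_depleted = unname(control_depleted),
    eligible = unname(treatment_pass & !control_depleted),
    stringsAsFactors = FALSE
  )
  attr(out, "thresholds") <- list(t1 = t1_thresh, t2 = t2_thresh,
                                  c1 = c1_thresh, c2 = c2_thresh,
                                  combine = combine)
  class(out) <- c("sgrna_flags", "data.frame")
  out
}

#' Call hit genes from flagged sgRNAs
#'
#' A gene is a hit when it is not on the viability-exclusion list and at
#' least `min_support` distinct sgRNAs targeting it are eligible. Output is
#' sorted by descending eligible-sgRNA count, then gene symbol, for stable
#' reports.
#'
#' @param flags An `sgrna_flags` data frame from [flag_sgrnas()].
#' @param lib A [library_design] mapping sgRNAs to genes.
#' @param excluded_genes Character vector of viability-depleted genes (from
#'   [viability_depleted_genes()]); these can never be hits.
#' @param min_support Minimum number of eligible sgRNAs per hit (default 2:
#'   at least two independent guides must score).
#' @param include_controls If `FALSE` (default) control-category genes are
#'   not called as hits.
#' @return A data frame of class `hit_table`: `gene`, `n_eligible`, `hit`,
#'   `excluded_viability`, `supporting_sgrnas` (comma-separated ids).
#' @export
call_hits <- function(flags, lib, excluded_genes = character(0),
                      min_support = 2L, include_controls = FALSE) {
  stopifnot(inherits(flags, "sgrna_flags"), inherits(lib, "library_design"),
            min_support >= 1L)
  unknown <- setdiff(flags$sgrna_id, lib$sgrna_id)
  if (length(unknown) > 0L) {
    stop("flagged sgRNA(s) absent from library: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  gene_of <- setNames(lib$gene, lib$sgrna_id)
  gene_cat <- unique(as.data.frame(lib)[, c("gene", "category")])
  cat_of <- setNames(gene_cat$category, gene_cat$gene)

  flags$gene <- unname(gene_of[flags$sgrna_id])
  genes <- sort(unique(flags$gene))
  elig_by_gene <- split(flags$sgrna_id[flags$eligible],
                        flags$gene[flags$eligible])
  n_eligible <- vapply(genes, function(g) {
    length(elig_by_gene[[g]] %||% character(0))
  }, integer(1))
  supporting <- vapply(genes, function(g) {
    paste(sort(elig_by_gene[[g]] %||% character(0)), collapse = ",")
  }, character(1))
  excluded <- genes %in% excluded_genes
  is_control <- cat_of[genes] %in% CONTROL_CATEGORIES
  hit <- !excluded & n_eligible >= min_support
  if (!isTRUE(include_controls)) hit <- hit & !is_control

  out <- data.frame(gene = genes,
                    n_eligible = unname(n_eligible),
                    hit = unname(hit),
                    excluded_viability = unname(excluded),
                    supporting_sgrnas = unname(supporting),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_eligible, out$gene), ]
  rownames(out) <- NULL
  attr(out, "min_support") <- as.integer(min_support)
  attr(out, "thresholds") <- attr(flags, "thresholds")
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Compare called hits with planted simulation truth
#'
#' Precision and recall of the hit calls against the planted hit labels of a
#' synthetic screen. Only non-control (target) genes are scored.
#'
#' @param hits A `hit_table` from [call_hits()].
#' @param truth A `simulation_truth` from [simulate_truth()].
#' @return A list with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`
#'   (`NA` where the denominator is zero).
#' @export
evaluate_recovery <- function(hits, truth) {
  stopifnot(inherits(hits, "hit_table"), inherits(truth, "simulation_truth"))
  tg <- truth$genes[truth$genes$category == "target", ]
  missing_genes <- setdiff(tg$gene, hits$gene)
  if (length(missing_genes) > 0L) {
    stop("hit table does not cover truth gene(s): ",
         paste(utils::head(missing_genes, 5L), collapse = ", "),
         call. = FALSE)
  }
  called <- setNames(hits$hit, hits$gene)[tg$gene]
  planted <- tg$class == "tcell_hit"
  tp <- sum(called & planted)
  fp <- sum(called & !planted)
  fn <- sum(!called & planted)
  tn <- sum(!called & !planted)
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  )
}

#' Write a hit table as TSV
#'
#' @param hits A `hit_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
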