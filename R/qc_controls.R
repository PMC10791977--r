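#' Score essential and non-essential control genes
#'
#' A dropout screen is trusted when guides against essential (viability)
#' control genes fall out of the pool while guides against non-essential
#' controls stay put. An essential control counts as depleted when its mean
#' log2 fold change in the viability contrast is at or below
#' `depleted_threshold` (at-least-fourfold depletion at the default -2,
#' inclusive); a non-essential control counts as stable when its mean is
#' strictly above `stable_threshold` (default -1).
#'
#' @param summary A `gene_summary` from [gene_mean_fc()].
#' @param viability_contrast Name of the contrast column measuring depletion
#'   after knockout in the absence of treatment (e.g. `"T0vsRef"`).
#' @param depleted_threshold Inclusive upper bound for calling an essential
#'   control depleted (default -2).
#' @param stable_threshold Exclusive lower bound for calling a non-essential
#'   control stable (default -1).
#' @return A list of class `qc_report`: totals, depleted/stable counts,
#'   fractions (NA with a warning when a category has no genes), and the
#'   thresholds used.
#' @export
control_qc <- function(summary, viability_contrast,
                       depleted_threshold = -2, stable_threshold = -1) {
  stopifnot(inherits(summary, "gene_summary"))
  if (!viability_contrast %in% names(summary)) {
    stop("contrast '", viability_contrast, "' not found in gene summary",
         call. = FALSE)
  }
  vals <- summary[[viability_contrast]]
  ess <- summary$category == "essential_control"
  non <- summary$category == "nonessential_control"
  essential_total <- sum(ess)
  nonessential_total <- sum(non)
  essential_depleted <- sum(ess & vals <= depleted_threshold)
  nonessential_stable <- sum(non & vals > stable_threshold)
  frac <- function(k, n, what) {
    if (n == 0L) {
      warning("no ", what, " control genes in summary; fraction undefined",
              call. = FALSE)
      return(NA_real_)
    }
    k / n
  }
  out <- list(
    essential_total = essential_total,
    essential_depleted = essential_depleted,
    essential_depletion_fraction =
      frac(essential_depleted, essential_total, "essential"),
    nonessential_total = nonessential_total,
    nonessential_stable = nonessential_stable,
    nonessential_stable_fraction =
      frac(nonessential_stable, nonessential_total, "non-essential"),
    viability_contrast = viability_contrast,
    depleted_threshold = depleted_threshold,
    stable_threshold = stable_threshold
  )
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("control QC on contrast", x$viability_contrast, "\n")
  cat(sprintf("  essential controls depleted (mean log2FC <= %g): %d/%d (%s)\n",
              x$depleted_threshold, x$essential_depleted, x$essential_total,
              fmt_pct(x$essential_depletion_fraction)))
  cat(sprintf("  non-essential controls stable (mean log2FC > %g): %d/%d (%s)\n",
              x$stable_threshold, x$nonessential_stable,
              x$nonessential_total, fmt_pct(x$nonessential_stable_fraction)))
  invisible(x)
}

fmt_pct <- function(p) {
  if (is.na(p)) "NA" else sprintf("%.1f%%", 100 * p)
}

#' Identify viability-depleted genes
#'
#' Genes depleted at least `abs(threshold)`-fold on average in the viability
#' contrast (inclusive: mean log2 fold change <= threshold) are putatively
#' essential for growth or division and are excluded from treatment-specific
#' hit calling. Control-category genes are kept out of the returned set by
#' default so they remain visible to QC reporting.
#'
#' @inheritParams control_qc
#' @param threshold Inclusive depletion bound (default -2, i.e. fourfold).
#' @param include_controls If `TRUE`, control-category genes may also be
#'   returned.
#' @return Sorted character vector of gene symbols.
#' @export
viability_depleted_genes <- function(summary, viability_contrast,
                                     threshold = -2,
                                     include_controls = FALSE) {
  stopifnot(inherits(summary, "gene_summary"))
  if (!viability_contrast %in% names(summary)) {
    stop("contrast '", viability_contrast, "' not found in gene summary",
         call. = FALSE)
  }
  keep <- summary[[viability_contrast]] <= threshold
  if (!isTRUE(include_controls)) {
    keep <- keep & summary$category == "target"
  }
  sort(summary$gene[keep])
}
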