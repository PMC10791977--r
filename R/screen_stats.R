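#' Normalise counts to frequencies
#'
#' Converts raw sgRNA counts to reads-per-`scale` frequencies with a
#' symmetric pseudocount: `f[i, s] = (c[i, s] + pseudocount) /
#' sum_j(c[j, s] + pseudocount) * scale`. Every column sums to `scale`, and
#' the pseudocount guarantees strictly positive frequencies, hence finite
#' log fold changes downstream.
#'
#' @param counts A `count_matrix` (sgRNAs x samples) or plain non-negative
#'   matrix with dimnames.
#' @param pseudocount Positive value added to every entry before
#'   normalisation (default 0.5, standard for dropout screens).
#' @param scale Target column sum (default 1e6, i.e. reads per million).
#' @return A numeric matrix of frequencies with the input dimnames.
#' @export
normalize_counts <- function(counts, pseudocount = 0.5, scale = 1e6) {
  stopifnot(is.matrix(counts) || inherits(counts, "count_matrix"))
  m <- unclass(counts)
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  zero_cols <- colSums(m) == 0
  if (any(zero_cols)) {
    warning("all-zero count column(s): ",
            paste(colnames(m)[zero_cols], collapse = ", "),
            " (uniform frequencies reported)", call. = FALSE)
  }
  m <- m + pseudocount
  sweep(m, 2L, colSums(m), "/") * scale
}

#' Define a fold-change contrast
#'
#' @param name Contrast label (e.g. `"T1vsT0"`).
#' @param numerator Sample label of the later/treated sample.
#' @param denominator Sample label of the baseline, or `"library_uniform"`
#'   for the expected uniform frequency `scale / n_sgRNAs` (used when no
#'   sequenced plasmid reference is available).
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(name, numerator, denominator) {
  stopifnot(is.character(name), is.character(numerator),
            is.character(denominator), numerator != denominator)
  structure(list(name = name, numerator = numerator,
                 denominator = denominator),
            class = "contrast_spec")
}

#' Default screen contrasts
#'
#' The two-arm time course: T1/T2 (treatment rounds with engager + T cells)
#' and C1/C2 (T cells without engager) are each compared with the
#' post-transduction baseline T0; the viability contrast compares T0 with a
#' reference (`"library_uniform"` unless a sequenced plasmid-pool sample is
#' named).
#'
#' @param viability_reference Denominator for the viability contrast.
#' @return List of [contrast_spec] objects.
#' @export
default_contrasts <- function(viability_reference = "library_uniform") {
  list(
    contrast_spec("T0vsRef", "T0", viability_reference),
    contrast_spec("T1vsT0", "T1", "T0"),
    contrast_spec("T2vsT0", "T2", "T0"),
    contrast_spec("C1vsT0", "C1", "T0"),
    contrast_spec("C2vsT0", "C2", "T0")
  )
}

#' Per-sgRNA log2 fold changes for a set of contrasts
#'
#' `log2fc[i, k] = log2(f[i, num_k] / f[i, den_k])` on the normalised
#' frequency matrix. A `"library_uniform"` denominator resolves to
#' `scale / n_sgRNAs` for every sgRNA.
#'
#' @param freq Frequency matrix from [normalize_counts()].
#' @param contrasts List of [contrast_spec] objects.
#' @param scale The scale used during normalisation (needed only for
#'   `"library_uniform"` denominators; default 1e6).
#' @return A numeric matrix of class `fold_change_table`, sgRNAs x contrasts.
#' @export
log2_fold_changes <- function(freq, contrasts, scale = 1e6) {
  stopifnot(is.matrix(freq))
  if (inherits(contrasts, "contrast_spec")) contrasts <- list(contrasts)
  cols <- lapply(contrasts, function(ct) {
    if (!ct$numerator %in% colnames(freq)) {
      stop("contrast '", ct$name, "': unknown sample label '", ct$numerator,
           "'", call. = FALSE)
    }
    num <- freq[, ct$numerator]
    den <- if (identical(ct$denominator, "library_uniform")) {
      rep(scale / nrow(freq), nrow(freq))
    } else {
      if (!ct$denominator %in% colnames(freq)) {
        stop("contrast '", ct$name, "': unknown sample label '",
             ct$denominator, "'", call. = FALSE)
      }
      freq[, ct$denominator]
    }
    log2(num / den)
  })
  fc <- do.call(cbind, cols)
  dimnames(fc) <- list(rownames(freq), vapply(contrasts, `[[`, "", "name"))
  class(fc) <- c("fold_change_table", class(fc))
  fc
}

#' Per-gene mean fold changes
#'
#' Unweighted arithmetic mean of each gene's sgRNA log2 fold changes, per
#' contrast, with the sgRNA support count and the gene's control category.
#'
#' @param fc A `fold_change_table` (sgRNAs x contrasts).
#' @param lib A [library_design] covering every sgRNA in `fc`.
#' @return A data frame of class `gene_summary`: `gene`, `category`,
#'   `n_sgrnas`, then one column per contrast.
#' @export
gene_mean_fc <- function(fc, lib) {
  stopifnot(inherits(fc, "fold_change_table") || is.matrix(fc),
            inherits(lib, "library_design"))
  gene_of <- setNames(lib$gene, lib$sgrna_id)
  missing_ids <- setdiff(rownames(fc), lib$sgrna_id)
  if (length(missing_ids) > 0L) {
    stop("sgRNA(s) absent from library: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  genes <- gene_of[rownames(fc)]
  sums <- rowsum(unclass(fc), group = genes, reorder = TRUE)
  n <- as.integer(table(genes)[rownames(sums)])
  means <- sums / n
  gene_cat <- unique(as.data.frame(lib)[, c("gene", "category")])
  cat_of <- setNames(gene_cat$category, gene_cat$gene)
  out <- data.frame(gene = rownames(means),
                    category = unname(cat_of[rownames(means)]),
                    n_sgrnas = n,
                    means,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_summary", "data.frame")
  out
}

#' Write fold-change and gene-summary tables
#'
#' Fold-change TSV layout: `sgrna_id  gene  <contrast...>`; gene summary:
#' `gene  category  n_sgrnas  <contrast...>`.
#'
#' @param fc A `fold_change_table`.
#' @param lib A [library_design].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(fc, lib, path) {
  gene <- setNames(lib$gene, lib$sgrna_id)[rownames(fc)]
  df <- data.frame(sgrna_id = rownames(fc), gene = unname(gene),
                   unclass(fc), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param summary A `gene_summary`.
#' @rdname write_fold_changes
#' @export
write_gene_summary <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_changes
#' @export
read_gene_summary <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  needed <- c("gene", "category", "n_sgrnas")
  if (!all(needed %in% names(df))) {
    stop("gene summary must have gene, category and n_sgrnas columns",
         call. = FALSE)
  }
  class(df) <- c("gene_summary", "data.frame")
  df
}
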