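#' sgRNA library design objects
#'
#' A `library_design` is a data frame with one row per sgRNA and columns
#' `sgrna_id`, `gene`, `sequence` (the protospacer) and `category` (one of
#' `target`, `essential_control`, `nonessential_control`), carrying the two
#' cassette flank sequences as attributes. Row order is meaningful and
#' preserved through I/O.
#'
#' @param records Data frame with columns `sgrna_id`, `gene`, `sequence` and
#'   optionally `category` (defaults to `"target"`).
#' @param flank5,flank3 Fixed vector sequences surrounding the protospacer in
#'   the sequenced cassette.
#' @param enforce_length If `TRUE`, reject protospacers outside 18-23 nt (the
#'   range seen in real designs); the default tolerates toy sequences for
#'   testing and pattern construction. [read_library_table()] enforces it.
#' @return An object of class `library_design`.
#' @export
library_design <- function(records, flank5 = DEFAULT_FLANK5,
                           flank3 = DEFAULT_FLANK3, enforce_length = FALSE) {
  stopifnot(is.data.frame(records))
  required <- c("sgrna_id", "gene", "sequence")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("library is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("library must contain at least one sgRNA record", call. = FALSE)
  }
  records$sgrna_id <- as.character(records$sgrna_id)
  records$gene <- as.character(records$gene)
  records$sequence <- toupper(as.character(records$sequence))
  if (is.null(records$category)) records$category <- "target"
  records$category <- as.character(records$category)

  dup <- records$sgrna_id[duplicated(records$sgrna_id)]
  if (length(dup) > 0L) {
    stop("duplicate sgrna_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_seq <- which(!grepl("^[ACGT]+$", records$sequence))
  if (length(bad_seq) > 0L) {
    stop("non-ACGT protospacer sequence at row ", bad_seq[1L], ": ",
         records$sequence[bad_seq[1L]], call. = FALSE)
  }
  if (isTRUE(enforce_length)) {
    bad_len <- which(nchar(records$sequence) < 18L |
                       nchar(records$sequence) > 23L)
    if (length(bad_len) > 0L) {
      stop("protospacer length outside 18-23 nt at row ", bad_len[1L],
           " (length ", nchar(records$sequence[bad_len[1L]]), ")",
           call. = FALSE)
    }
  }
  bad_cat <- which(!records$category %in% SGRNA_CATEGORIES)
  if (length(bad_cat) > 0L) {
    stop("unknown category at row ", bad_cat[1L], ": ",
         records$category[bad_cat[1L]], call. = FALSE)
  }
  for (fl in list(flank5 = flank5, flank3 = flank3)) {
    if (!is.character(fl) || length(fl) != 1L || !grepl("^[ACGT]*$", fl)) {
      stop("flanks must be single ACGT strings", call. = FALSE)
    }
  }

  out <- records[, c("sgrna_id", "gene", "sequence", "category")]
  rownames(out) <- NULL
  attr(out, "flank5") <- toupper(flank5)
  attr(out, "flank3") <- toupper(flank3)
  class(out) <- c("library_design", "data.frame")
  out
}

#' Read an sgRNA library table
#'
#' Reads a tab-separated library file with a header row and columns
#' `sgrna_id`, `gene`, `sequence` and optionally `category`. Lines starting
#' with `#` are ignored. `column_map` remaps differently named headers onto
#' the canonical ones, e.g. `c(sgrna_id = "guide", sequence = "spacer")`.
#'
#' @param path Path to a TSV file (plain or gzip-compressed).
#' @param column_map Optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @param flank5,flank3 Cassette flank sequences to attach to the design.
#' @return A [library_design] with records in file order.
#' @export
read_library_table <- function(path, column_map = NULL,
                               flank5 = DEFAULT_FLANK5,
                               flank3 = DEFAULT_FLANK3) {
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(tab)) {
        stop("column_map refers to missing column '", src, "'", call. = FALSE)
      }
      names(tab)[names(tab) == src] <- canonical
    }
  }
  required <- c("sgrna_id", "gene", "sequence")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("library file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  library_design(tab, flank5 = flank5, flank3 = flank3, enforce_length = TRUE)
}

#' Write an sgRNA library table
#'
#' Inverse of [read_library_table()]: writes the canonical tab-separated
#' dialect so that a read-back reproduces the design (flanks are not stored
#' in the file and must be re-supplied if non-default).
#'
#' @param lib A [library_design].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_table <- function(lib, path) {
  stopifnot(inherits(lib, "library_design"))
  utils::write.table(as.data.frame(lib), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a library and summarise its composition
#'
#' Pure reporting: counts per category, per-gene sgRNA count range, genes per
#' category, duplicated protospacer sequences (legal, but a source of
#' ambiguous reads downstream) and, on request, the minimum pairwise Hamming
#' distance among equal-length protospacers.
#'
#' @param lib A [library_design].
#' @param min_hamming If `TRUE`, also compute the minimum pairwise Hamming
#'   distance among equal-length protospacers (quadratic; intended for small
#'   or sampled libraries).
#' @return A list of class `library_validation` with components
#'   `n_sgrnas`, `n_genes`, `category_counts`, `genes_per_category`,
#'   `per_gene_range`, `duplicate_sequences` and optionally `min_hamming`.
#' @export
validate_library <- function(lib, min_hamming = FALSE) {
  stopifnot(inherits(lib, "library_design"))
  per_gene <- table(lib$gene)
  cat_counts <- table(factor(lib$category, levels = SGRNA_CATEGORIES))
  gene_cat <- unique(as.data.frame(lib)[, c("gene", "category")])
  genes_per_cat <- table(factor(gene_cat$category, levels = SGRNA_CATEGORIES))
  dup_seq <- unique(lib$sequence[duplicated(lib$sequence)])
  out <- list(
    n_sgrnas = nrow(lib),
    n_genes = length(per_gene),
    category_counts = as.integer(cat_counts),
    genes_per_category = as.integer(genes_per_cat),
    per_gene_range = c(min = min(per_gene), max = max(per_gene)),
    duplicate_sequences = dup_seq
  )
  names(out$category_counts) <- SGRNA_CATEGORIES
  names(out$genes_per_category) <- SGRNA_CATEGORIES
  if (isTRUE(min_hamming)) {
    out$min_hamming <- min_pairwise_hamming(lib$sequence)
  }
  class(out) <- "library_validation"
  out
}

#' @export
print.library_validation <- function(x, ...) {
  cat("sgRNA library:", x$n_sgrnas, "sgRNAs over", x$n_genes, "genes\n")
  cat("  per category:",
      paste(names(x$category_counts), x$category_counts, collapse = ", "),
      "\n")
  cat("  genes per category:",
      paste(names(x$genes_per_category), x$genes_per_category,
            collapse = ", "), "\n")
  cat("  sgRNAs per gene:", x$per_gene_range["min"], "-",
      x$per_gene_range["max"], "\n")
  cat("  duplicated protospacers:", length(x$duplicate_sequences), "\n")
  if (!is.null(x$min_hamming)) {
    cat("  min pairwise Hamming distance:", x$min_hamming, "\n")
  }
  invisible(x)
}

min_pairwise_hamming <- function(seqs) {
  by_len <- split(unique(seqs), nchar(unique(seqs)))
  best <- Inf
  for (grp in by_len) {
    if (length(grp) < 2L) next
    best <- min(best, min_hamming_cpp(grp))
  }
  if (is.infinite(best)) NA_integer_ else as.integer(best)
}

#' Build flank-anchored query patterns
#'
#' Each sgRNA's cassette pattern is the concatenation
#' `flank5 + protospacer + flank3`; reads are assigned by approximate matching
#' against these patterns (see [best_match()]).
#'
#' @param lib A [library_design].
#' @return An object of class `pattern_set`: a data frame with `sgrna_id` and
#'   `cassette`, plus attribute `cassette_lengths` (the distinct lengths).
#' @export
build_query_patterns <- function(lib) {
  stopifnot(inherits(lib, "library_design"))
  cassette <- paste0(attr(lib, "flank5"), lib$sequence, attr(lib, "flank3"))
  out <- data.frame(sgrna_id = lib$sgrna_id, cassette = cassette,
                    stringsAsFactors = FALSE)
  attr(out, "cassette_lengths") <- sort(unique(nchar(cassette)))
  class(out) <- c("pattern_set", "data.frame")
  out
}
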