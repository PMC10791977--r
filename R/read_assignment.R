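#' Hamming distance between two equal-length sequences
#'
#' Substitution distance only (no indels). Any symbol outside A/C/G/T — such
#' as an `N` base call — mismatches every symbol, including itself, so that
#' uncalled bases always consume mismatch budget.
#'
#' @param a,b Equal-length nucleotide strings.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' mismatch_count("ACGT", "ACGA")  # 1
#' mismatch_count("NNNN", "NNNN")  # 4
#' @export
mismatch_count <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L)
  hamming_cpp(toupper(a), toupper(b))
}

#' Assign a read to its best-matching sgRNA cassette
#'
#' Scans every cassette pattern at every valid offset of the read. Among all
#' (pattern, offset) pairs within the mismatch budget, the minimal distance
#' wins; if two or more distinct sgRNAs attain the minimum the read is
#' discarded as ambiguous; if no pair qualifies it is unassigned. Equal-score
#' offsets of the *same* sgRNA are resolved to the leftmost offset and the
#' read stays assigned — the tie rule concerns distinct sgRNAs only.
#'
#' @param read A nucleotide string.
#' @param patterns A `pattern_set` from [build_query_patterns()].
#' @param max_mm Maximum number of mismatches tolerated (default 2).
#' @param revcomp If `TRUE`, additionally scan the reverse complement of the
#'   read; amplicon orientation is fixed by the primers so the default is off.
#' @return A list with `status` (`"assigned"`, `"ambiguous"` or
#'   `"unassigned"`), and for assigned reads `sgrna_id`, `offset` (0-based
#'   start of the cassette in the read; `NA` when matched on the reverse
#'   strand) and `mismatches`.
#' @export
best_match <- function(read, patterns, max_mm = 2L, revcomp = FALSE) {
  stopifnot(inherits(patterns, "pattern_set"), length(read) == 1L,
            max_mm >= 0L)
  res <- match_read_batch(toupper(read), patterns, max_mm, revcomp)
  list(
    status = res$status[1L],
    sgrna_id = res$sgrna_id[1L],
    offset = res$offset[1L],
    mismatches = res$mismatches[1L]
  )
}

match_read_batch <- function(reads, patterns, max_mm, revcomp) {
  rc <- NULL
  if (isTRUE(revcomp)) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reads))
    )
  }
  res <- match_reads_cpp(reads, patterns$cassette, as.integer(max_mm), rc)
  status <- c("unassigned", "assigned", "ambiguous")[res$status + 1L]
  sgrna_id <- rep(NA_character_, length(reads))
  hit <- res$status == 1L
  sgrna_id[hit] <- patterns$sgrna_id[res$pattern[hit]]
  offset <- res$offset
  offset[!is.na(offset) & offset < 0L] <- NA_integer_
  list(status = status, sgrna_id = sgrna_id, offset = offset,
       mismatches = res$mismatches)
}

#' Count reads per sgRNA in one FASTQ sample
#'
#' Applies [best_match()] to every read of a (possibly gzip-compressed)
#' single-end FASTQ file and tallies assigned reads per sgRNA. The returned
#' count vector covers every library sgRNA, zeros included, and the
#' statistics conserve totals: assigned + ambiguous + unassigned equals the
#' number of reads.
#'
#' @param fastq_path Path to a FASTQ or FASTQ.gz file.
#' @param patterns A `pattern_set` from [build_query_patterns()].
#' @param max_mm Mismatch budget per read (default 2).
#' @param revcomp Also scan reverse complements (default `FALSE`).
#' @param chunk_size Reads processed per batch (memory control).
#' @return A list with `counts` (named integer vector over all sgRNAs) and
#'   `stats` (an `assignment_stats` list: `total_reads`, `assigned`,
#'   `ambiguous`, `unassigned`, `mismatch_histogram` indexed 0..max_mm).
#' @export
count_sample <- function(fastq_path, patterns, max_mm = 2L, revcomp = FALSE,
                         chunk_size = 200000L) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (!file.exists(fastq_path)) {
    stop("FASTQ file not found: ", fastq_path, call. = FALSE)
  }
  reads <- read_fastq_sequences(fastq_path)
  counts <- setNames(integer(nrow(patterns)), patterns$sgrna_id)
  n_total <- length(reads)
  n_assigned <- 0L
  n_ambiguous <- 0L
  mm_hist <- setNames(integer(max_mm + 1L), as.character(0:max_mm))
  idx <- seq_len(n_total)
  for (chunk in split(idx, ceiling(idx / chunk_size))) {
    res <- match_read_batch(toupper(reads[chunk]), patterns, max_mm, revcomp)
    assigned <- res$status == "assigned"
    n_assigned <- n_assigned + sum(assigned)
    n_ambiguous <- n_ambiguous + sum(res$status == "ambiguous")
    if (any(assigned)) {
      tab <- table(res$sgrna_id[assigned])
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
      mm_tab <- table(factor(res$mismatches[assigned], levels = 0:max_mm))
      mm_hist <- mm_hist + as.integer(mm_tab)
    }
  }
  stats <- list(
    total_reads = n_total,
    assigned = n_assigned,
    ambiguous = n_ambiguous,
    unassigned = n_total - n_assigned - n_ambiguous,
    mismatch_histogram = mm_hist
  )
  class(stats) <- "assignment_stats"
  list(counts = counts, stats = stats)
}

#' @export
print.assignment_stats <- function(x, ...) {
  cat("reads:", x$total_reads, "| assigned:", x$assigned, "| ambiguous:",
      x$ambiguous, "| unassigned:", x$unassigned, "\n")
  cat("mismatches among assigned:",
      paste0(names(x$mismatch_histogram), "=", x$mismatch_histogram,
             collapse = " "), "\n")
  invisible(x)
}

# Sequences only; qualities are not used anywhere downstream. Records are
# required to be strict 4-line FASTQ; a truncated or malformed record is
# reported with its record index.
read_fastq_sequences <- function(path) {
  if (file.size(path) == 0L) return(character(0))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ file ", path, ": truncated record ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  }
  headers <- lines[seq(1L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(headers, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0L) {
    stop("malformed FASTQ file ", path, ": record ", bad[1L],
         " lacks @/+ structure", call. = FALSE)
  }
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  short <- which(nchar(quals) != nchar(seqs))
  if (length(short) > 0L) {
    stop("malformed FASTQ file ", path, ": record ", short[1L],
         " has mismatched sequence/quality lengths", call. = FALSE)
  }
  seqs
}

#' Assemble a count matrix from per-sample count vectors
#'
#' @param samples Named list of count vectors (one per sample, e.g.
#'   `list(T0 = ..., T1 = ...)`), each indexed by the same sgRNA set in the
#'   same order.
#' @return An integer matrix of class `count_matrix`, sgRNAs x samples,
#'   columns in input order.
#' @export
build_count_matrix <- function(samples) {
  stopifnot(is.list(samples), length(samples) > 0L)
  if (is.null(names(samples)) || any(names(samples) == "")) {
    stop("every sample must be named", call. = FALSE)
  }
  if (anyDuplicated(names(samples))) {
    stop("duplicate sample labels", call. = FALSE)
  }
  ref_ids <- names(samples[[1L]])
  if (is.null(ref_ids)) stop("count vectors must be named by sgrna_id",
                             call. = FALSE)
  for (s in names(samples)) {
    v <- samples[[s]]
    if (!identical(names(v), ref_ids)) {
      stop("sample '", s, "' is not indexed by the same sgRNA set",
           call. = FALSE)
    }
    if (any(v < 0)) stop("negative counts in sample '", s, "'", call. = FALSE)
  }
  m <- do.call(cbind, lapply(samples, as.integer))
  dimnames(m) <- list(ref_ids, names(samples))
  class(m) <- c("count_matrix", class(m))
  m
}

#' Write / read a count matrix as TSV
#'
#' Layout: `sgrna_id  gene  <sample...>`, one row per sgRNA. The gene column
#' is taken from the library design.
#'
#' @param counts A `count_matrix`.
#' @param lib A [library_design] covering the same sgRNAs.
#' @param path Output TSV path.
#' @return `path` invisibly (writer); a `count_matrix` (reader).
#' @export
write_count_matrix <- function(counts, lib, path) {
  stopifnot(inherits(lib, "library_design"))
  gene <- setNames(lib$gene, lib$sgrna_id)[rownames(counts)]
  df <- data.frame(sgrna_id = rownames(counts), gene = unname(gene),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  needed <- c("sgrna_id", "gene")
  if (!all(needed %in% names(df))) {
    stop("count table must have sgrna_id and gene columns", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), needed), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sgrna_id
  class(m) <- c("count_matrix", class(m))
  m
}
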