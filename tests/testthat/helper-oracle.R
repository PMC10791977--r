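# Independent exhaustive scorer used to cross-check the compiled matcher.
# Deliberately naive: plain R, no early exit, scores every pattern at every
# offset and applies the decision rule from first principles.

oracle_base_match <- function(x, y) {
  x == y & x %in% c("A", "C", "G", "T")
}

oracle_mismatches <- function(read_chars, pat_chars, offset) {
  slice <- read_chars[offset:(offset + length(pat_chars) - 1L)]
  sum(!oracle_base_match(slice, pat_chars))
}

oracle_best_match <- function(read, patterns, max_mm = 2L) {
  read_chars <- strsplit(read, "")[[1]]
  hits <- list()
  for (j in seq_len(nrow(patterns))) {
    pat_chars <- strsplit(patterns$cassette[j], "")[[1]]
    n_off <- length(read_chars) - length(pat_chars) + 1L
    if (n_off < 1L) next
    for (o in seq_len(n_off)) {
      d <- oracle_mismatches(read_chars, pat_chars, o)
      if (d <= max_mm) {
        hits[[length(hits) + 1L]] <-
          list(id = patterns$sgrna_id[j], offset = o - 1L, d = d)
      }
    }
  }
  if (length(hits) == 0L) {
    return(list(status = "unassigned", sgrna_id = NA_character_,
                offset = NA_integer_, mismatches = NA_integer_))
  }
  ds <- vapply(hits, `[[`, numeric(1), "d")
  best <- hits[ds == min(ds)]
  ids <- unique(vapply(best, `[[`, character(1), "id"))
  if (length(ids) > 1L) {
    return(list(status = "ambiguous", sgrna_id = NA_character_,
                offset = NA_integer_, mismatches = as.integer(min(ds))))
  }
  offs <- vapply(best, `[[`, numeric(1), "offset")
  list(status = "assigned", sgrna_id = ids,
       offset = as.integer(min(offs)), mismatches = as.integer(min(ds)))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random matcher test instance: a small pattern set (short toy flanks so that
# approximate hits are actually reachable) plus one read that may embed a
# mutated cassette or be pure noise
random_match_instance <- function(max_patterns = 12L, read_len = 60L) {
  n_pat <- sample.int(max_patterns, 1L)
  flank5 <- random_seq(sample(0:4, 1L))
  flank3 <- random_seq(sample(0:4, 1L))
  proto_len <- sample(6:10, 1L)
  lib <- library_design(
    data.frame(sgrna_id = paste0("g", seq_len(n_pat)),
               gene = paste0("G", seq_len(n_pat)),
               sequence = vapply(seq_len(n_pat), function(i)
                 random_seq(proto_len), character(1))),
    flank5 = flank5, flank3 = flank3
  )
  patterns <- build_query_patterns(lib)
  rl <- sample(seq(nchar(patterns$cassette[1L]), read_len), 1L)
  if (runif(1) < 0.75) {
    # embed a cassette with a few substitutions (sometimes N) somewhere
    cas <- strsplit(sample(patterns$cassette, 1L), "")[[1]]
    n_mut <- sample(0:3, 1L)
    if (n_mut > 0L) {
      pos <- sample(length(cas), n_mut)
      cas[pos] <- sample(c("A", "C", "G", "T", "N"), n_mut, replace = TRUE)
    }
    pad <- rl - length(cas)
    pre <- sample(0:pad, 1L)
    read <- paste0(random_seq(pre), paste(cas, collapse = ""),
                   random_seq(pad - pre))
  } else {
    read <- random_seq(rl, alphabet = c("A", "C", "G", "T", "N"))
  }
  list(patterns = patterns, read = read)
}
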