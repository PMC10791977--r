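test_that("mismatch_count is Hamming distance with a strict N policy", {
  expect_equal(mismatch_count("ACGT", "ACGT"), 0L)
  expect_equal(mismatch_count("ACGT", "ACGA"), 1L)
  expect_equal(mismatch_count("NNNN", "NNNN"), 4L)
  expect_equal(mismatch_count("ANGT", "ACGT"), 1L)
  expect_error(mismatch_count("ACG", "ACGT"), "equal length")
})

test_that("best_match assigns a planted exact cassette at its offset", {
  lib <- toy_library()
  pats <- build_query_patterns(lib)
  read <- paste0("TT", pats$cassette[1L], "CC")
  res <- best_match(read, pats)
  expect_identical(res$status, "assigned")
  expect_identical(res$sgrna_id, "g1")
  expect_equal(res$offset, 2L)
  expect_equal(res$mismatches, 0L)
})

test_that("reads beyond the mismatch budget are unassigned", {
  lib <- toy_library()
  pats <- build_query_patterns(lib)
  cas <- pats$cassette[1L]
  mutated <- cas
  for (p in c(15L, 20L, 25L)) {
    old <- substr(mutated, p, p)
    substr(mutated, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  }
  expect_identical(best_match(mutated, pats, max_mm = 2L)$status,
                   "unassigned")
  expect_identical(best_match(mutated, pats, max_mm = 3L)$status,
                   "assigned")
  short <- substr(cas, 1L, 10L)
  expect_identical(best_match(short, pats)$status, "unassigned")
})

test_that("ties between distinct sgRNAs are discarded as ambiguous", {
  # two guides differing at exactly one position; a read carrying a third
  # base at that position is at distance 1 from both
  proto1 <- "ACGTACGTACGTACGTACGT"
  proto2 <- "ACGTACGTACGTACGTACGA"
  lib <- library_design(data.frame(sgrna_id = c("g1", "g2"),
                                   gene = c("A", "B"),
                                   sequence = c(proto1, proto2)))
  pats <- build_query_patterns(lib)
  read <- paste0(attr(lib, "flank5"), "ACGTACGTACGTACGTACGC",
                 attr(lib, "flank3"))
  res <- best_match(read, pats)
  expect_identical(res$status, "ambiguous")
  expect_identical(oracle_best_match(read, pats)$status, "ambiguous")

  # a read matching one guide exactly is assigned despite the near-tie
  exact <- pats$cassette[1L]
  expect_identical(best_match(exact, pats)$sgrna_id, "g1")
})

test_that("equal-distance offsets of the same sgRNA resolve to the leftmost", {
  lib <- library_design(data.frame(sgrna_id = "g1", gene = "A",
                                   sequence = "ACGTACGTACGTACGTACGT"))
  pats <- build_query_patterns(lib)
  read <- paste0(pats$cassette, pats$cassette)
  res <- best_match(read, pats)
  expect_identical(res$status, "assigned")
  expect_equal(res$offset, 0L)
})

test_that("compiled matcher agrees with the exhaustive oracle", {
  set.seed(101)
  for (i in 1:60) {
    inst <- random_match_instance()
    got <- best_match(inst$read, inst$patterns, max_mm = 2L)
    want <- oracle_best_match(inst$read, inst$patterns, max_mm = 2L)
    expect_identical(got[c("status", "sgrna_id", "offset", "mismatches")],
                     want[c("status", "sgrna_id", "offset", "mismatches")],
                     info = paste("instance", i, inst$read))
  }
})

test_that("count_sample conserves read totals and covers all sgRNAs", {
  lib <- toy_library()
  pats <- build_query_patterns(lib)
  set.seed(11)
  good <- c(rep(paste0("AA", pats$cassette[1L]), 50L),
            rep(paste0(pats$cassette[3L], "TT"), 40L))
  junk <- vapply(1:10, function(i) random_seq(50L), character(1))
  path <- withr::local_tempfile(fileext = ".fq")
  write_toy_fastq(sample(c(good, junk)), path)
  res <- count_sample(path, pats)
  st <- res$stats
  expect_equal(st$total_reads, 100L)
  expect_equal(st$assigned + st$ambiguous + st$unassigned, st$total_reads)
  expect_equal(st$unassigned, 10L)
  expect_equal(st$assigned + st$ambiguous, 90L)
  expect_equal(sum(res$counts), st$assigned)
  expect_equal(sum(st$mismatch_histogram), st$assigned)
  expect_named(res$counts, lib$sgrna_id)
  expect_equal(unname(res$counts[c("g1", "g3")]), c(50L, 40L))
  expect_equal(unname(res$counts[c("g2", "g4")]), c(0L, 0L))

  # determinism: same file, same outputs
  expect_identical(count_sample(path, pats), res)
})

test_that("lowering the mismatch budget never increases assignments", {
  lib <- toy_library()
  pats <- build_query_patterns(lib)
  set.seed(12)
  reads <- vapply(1:80, function(i) {
    cas <- strsplit(sample(pats$cassette, 1L), "")[[1]]
    pos <- sample(length(cas), sample(0:4, 1L))
    cas[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    paste0(random_seq(3L), paste(cas, collapse = ""), random_seq(3L))
  }, character(1))
  path <- withr::local_tempfile(fileext = ".fq")
  write_toy_fastq(reads, path)
  assigned <- vapply(0:4, function(mm) {
    count_sample(path, pats, max_mm = mm)$stats$assigned
  }, integer(1))
  expect_true(all(diff(assigned) >= 0L))
})

test_that("gzipped input and empty/malformed files are handled", {
  lib <- toy_library()
  pats <- build_query_patterns(lib)
  gz <- withr::local_tempfile(fileext = ".fq.gz")
  con <- gzfile(gz, "wb")
  writeLines(paste0("@r1\n", pats$cassette[2L], "\n+\n",
                    strrep("I", 44L)), con)
  close(con)
  res <- count_sample(gz, pats)
  expect_equal(unname(res$counts["g2"]), 1L)

  empty <- withr::local_tempfile(fileext = ".fq")
  file.create(empty)
  res0 <- count_sample(empty, pats)
  expect_equal(res0$stats$total_reads, 0L)
  expect_equal(sum(res0$counts), 0L)

  bad <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT"), bad)
  expect_error(count_sample(bad, pats), "malformed FASTQ")
  expect_error(count_sample("no_such_file.fq", pats), "not found")
})

test_that("reverse-complement scanning is off by default and works when on", {
  lib <- toy_library()
  pats <- build_query_patterns(lib)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pats$cassette[1L])))
  expect_identical(best_match(rc, pats)$status, "unassigned")
  res <- best_match(rc, pats, revcomp = TRUE)
  expect_identical(res$status, "assigned")
  expect_identical(res$sgrna_id, "g1")
})

test_that("count matrices assemble in sample order and validate inputs", {
  v1 <- c(g1 = 3L, g2 = 0L)
  v2 <- c(g1 = 1L, g2 = 7L)
  one <- build_count_matrix(list(S = v1))
  expect_equal(dim(one), c(2L, 1L))
  expect_equal(unname(one[, "S"]), unname(v1))

  five <- build_count_matrix(list(T0 = v1, T1 = v2, T2 = v1, C1 = v2,
                                  C2 = v1))
  expect_identical(colnames(five), c("T0", "T1", "T2", "C1", "C2"))

  perm <- build_count_matrix(list(T1 = v2, T0 = v1))
  expect_identical(colnames(perm), c("T1", "T0"))
  expect_equal(unname(perm[, "T0"]), unname(five[, "T0"]))

  expect_error(build_count_matrix(list(T0 = v1, T1 = c(g1 = 1L, gX = 2L))),
               "T1")
  expect_error(build_count_matrix(list(v1)), "named")
})

test_that("count matrix TSV round-trips through the library annotation", {
  lib <- toy_library()
  m <- build_count_matrix(list(
    T0 = setNames(c(5L, 2L, 9L, 1L), lib$sgrna_id),
    T1 = setNames(c(4L, 0L, 3L, 8L), lib$sgrna_id)
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, lib, path)
  back <- read_count_matrix(path)
  expect_equal(unclass(back), unclass(m))
})
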