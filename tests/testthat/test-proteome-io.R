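test_that("FASTA reading builds records with correct ids and lengths", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKV", ">P2", "MAAAA"), f)
  p <- read_proteome(f)
  expect_s3_class(p, "proteome")
  expect_length(p, 2L)
  expect_equal(unname(protein_lengths(p)), c(3L, 5L))
  expect_equal(protein_ids(p), c("P1", "P2"))
})

test_that("UniProt-style headers yield the accession as id", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|Q9M157|XXX_ARATH Some description", "MKVLLE"), f)
  expect_equal(protein_ids(read_proteome(f)), "Q9M157")
})

test_that("empty FASTA gives an empty proteome without error", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_length(read_proteome(f), 0L)
})

test_that("duplicate FASTA ids are rejected with the offending id named", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKV", ">P1", "MAAAA"), f)
  expect_error(read_proteome(f), "P1")
})

test_that("FASTA round trip is identity on ids and sequences", {
  p <- proteome(c(Z9 = "MKVA", A1 = "MHHE", M5 = "MWWW"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_proteome(p, f)
  p2 <- read_proteome(f)
  expect_identical(p2$seqs, p$seqs)
})

test_that("annotation rows populate existence, InterPro and GO fields", {
  p <- proteome(c(P1 = "MKV", P2 = "MAAAA", P3 = "MMM"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\t4\tIPR000001:Domain;IPR000002:Domain\tGO:0006355",
               "P2\t5\t\t"), f)
  p <- read_annotations(f, p)
  expect_equal(unname(p$existence[c("P1", "P2")]), c(4L, 5L))
  expect_equal(nrow(p$interpro[["P1"]]), 2L)
  expect_equal(p$interpro[["P1"]]$entry_type, c("Domain", "Domain"))
  expect_equal(p$go[["P1"]], "GO:0006355")
  # P2: explicit level, empty sets
  expect_null(p$interpro[["P2"]])
  expect_null(p$go[["P2"]])
  # P3: no row, unknown level, empty sets
  expect_true(is.na(p$existence[["P3"]]))
})

test_that("annotation rows for unknown proteins are skipped with a warning", {
  p <- proteome(c(P1 = "MKV"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\t2\t\t", "P9\t3\t\t"), f)
  expect_warning(p2 <- read_annotations(f, p), "P9")
  expect_length(p2, 1L)
  expect_equal(unname(p2$existence[["P1"]]), 2L)
})

test_that("malformed InterPro tokens and duplicate rows are errors", {
  p <- proteome(c(P1 = "MKV", P2 = "MAA"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("P1\t1\tIPR000001\t", f)
  expect_error(read_annotations(f, p), "IPR000001")
  writeLines(c("P1\t1\t\t", "P1\t2\t\t"), f)
  expect_error(read_annotations(f, p), "more than once")
})

test_that("annotation attachment changes neither record count nor sequences", {
  sim <- simulate_proteome(n_ancestors = 2, n_decoys_per_class = 2,
                           seed = 5, family_size = 0)
  p <- sim$proteome
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(p, f)
  bare <- proteome(p$seqs)
  p2 <- read_annotations(f, bare)
  expect_identical(p2$seqs, p$seqs)
  expect_identical(p2$existence, p$existence)
  expect_identical(p2$interpro[protein_ids(p)], p$interpro[protein_ids(p)])
})

test_that("OBO parsing maps GO ids to names", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0006355",
               "name: regulation of transcription", "",
               "[Term]", "id: GO:0009414", "name: response to water deprivation",
               "", "[Typedef]", "id: part_of", "name: part of"), f)
  nm <- read_go_obo(f)
  expect_equal(nm[["GO:0006355"]], "regulation of transcription")
  expect_length(nm, 2L)
})

test_that("pair table writing is rank-sorted and round-trips", {
  pairs <- data.frame(
    mip_id = c("M1", "M1", "M2"), target_id = c("T1", "T2", "T1"),
    bitscore = c(60, 45.5, 30.25), mip_length = c(100L, 100L, 80L),
    target_length = c(400L, 300L, 250L),
    coverage = c(0.25, 1 / 3, 0.32),
    instability_index = c(80.1, 80.1, 55.5),
    weight = c(0.76, 1.9, 1.5), score = c(3, 2, 1),
    single_copy = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  pairs <- rank_pairs(pairs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pairs, f)
  lines <- readLines(f)
  expect_length(lines, 4L)   # header + 3 rows
  back <- read_pairs(f)
  expect_equal(back$rank, 1:3)
  expect_equal(back$mip_id, pairs$mip_id)
  expect_equal(back$percentile, c(34L, 67L, 100L))
  # empty table: header only
  write_pairs(pairs[0, ], f)
  expect_length(readLines(f), 1L)
})

test_that("target GO extraction keeps only the best targets per microProtein", {
  p <- proteome(setNames(rep("MKVAMKVA", 13), c("M1", sprintf("T%02d", 1:12))),
                go = c(list(T01 = c("GO:A", "GO:B"), T02 = "GO:B"),
                       setNames(lapply(3:12, function(i) sprintf("GO:%02d", i)),
                                sprintf("T%02d", 3:12))))
  pairs <- data.frame(mip_id = "M1", target_id = sprintf("T%02d", 1:12),
                      score = seq(12, 1), stringsAsFactors = FALSE)
  go <- extract_target_go(pairs, p)
  # targets T01..T10 kept (scores 12..3); T11, T12 dropped
  expect_equal(go[1:3], c("GO:A", "GO:B", "GO:B"))  # duplicates preserved
  expect_false(any(c("GO:11", "GO:12") %in% go))
  expect_length(go, 3 + 8)
  expect_identical(extract_target_go(pairs[0, ], p), character(0))
})
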