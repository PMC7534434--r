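test_that("an identical database sequence is the top pairwise hit", {
  set.seed(11)
  db <- c(S1 = random_aa(100), S2 = random_aa(100), S3 = random_aa(100))
  hits <- pairwise_search(c(Q = db[["S2"]]), db)
  expect_equal(hits$subject_id[1L], "S2")
  expect_gt(hits$bitscore[1L], 30)
})

test_that("alphabet-disjoint sequences produce no hits above threshold", {
  q <- c(Q = strrep("W", 30))
  db <- c(D1 = strrep("P", 30), D2 = strrep("P", 30))
  hits <- pairwise_search(q, db, min_bitscore = 30)
  expect_equal(nrow(hits), 0L)
})

test_that("internal aligner matches the exhaustive enumeration oracle on tiny pairs", {
  set.seed(42)
  for (k in 1:6) {
    a <- random_aa(sample(3:5, 1), alphabet = c("A", "R", "N", "D", "C", "W"))
    b <- random_aa(sample(3:5, 1), alphabet = c("A", "R", "N", "D", "C", "W"))
    h <- pairwise_search(setNames(a, "q"), setNames(b, "s"))
    got <- if (nrow(h)) h$bitscore / internal_bits_per_raw else 0
    expect_equal(got, brute_local_enum(a, b), tolerance = 1e-9,
                 info = paste(a, b))
  }
})

test_that("internal aligner reproduces the textbook local alignment score", {
  a <- "HEAGAWGHEE"; b <- "PAWHEAE"
  h <- pairwise_search(c(q = a), c(s = b))
  raw <- h$bitscore / internal_bits_per_raw
  expect_equal(raw, oracle_local_dp(a, b), tolerance = 1e-9)
  # and the reported spans score back to the optimum
  expect_true(h$q_start >= 1 && h$q_end <= nchar(a))
  expect_true(h$s_start >= 1 && h$s_end <= nchar(b))
})

test_that("internal aligner agrees with an independent library aligner", {
  set.seed(7)
  for (k in 1:10) {
    a <- random_aa(sample(20:60, 1))
    b <- random_aa(sample(20:60, 1))
    h <- pairwise_search(c(q = a), c(s = b))
    raw <- if (nrow(h)) h$bitscore / internal_bits_per_raw else 0
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = blosum50, gapOpening = 10, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(raw, max(ref, 0), tolerance = 1e-9)
  }
})

test_that("pairwise scores are symmetric for the internal backend", {
  set.seed(3)
  for (k in 1:5) {
    a <- random_aa(40); b <- random_aa(50)
    ab <- pairwise_search(c(x = a), c(y = b))
    ba <- pairwise_search(c(y = b), c(x = a))
    expect_equal(nrow(ab), nrow(ba))
    if (nrow(ab)) expect_equal(ab$bitscore, ba$bitscore, tolerance = 1e-12)
  }
})

test_that("self-hits are excluded and results are deterministic", {
  set.seed(9)
  db <- setNames(replicate(4, random_aa(60)), paste0("P", 1:4))
  h1 <- pairwise_search(db, db)
  expect_false(any(h1$query_id == h1$subject_id))
  h2 <- pairwise_search(db, db)
  expect_identical(h1, h2)
  # sorted by descending bitscore with deterministic tie order
  expect_true(all(diff(h1$bitscore) <= 1e-12))
})

test_that("group alignment of identical sequences has no gaps", {
  prof <- align_group(c(a = "MKVAWE", b = "MKVAWE"))
  expect_false(any(grepl("-", prof$alignment, fixed = TRUE)))
  expect_equal(prof$consensus, "MKVAWE")
})

test_that("group alignment of MKVA and MKA introduces exactly one gap", {
  prof <- align_group(c(x = "MKVA", y = "MKA"))
  expect_equal(sum(strsplit(prof$alignment[["y"]], "")[[1L]] == "-"), 1L)
  expect_equal(nchar(prof$alignment[["x"]]), nchar(prof$alignment[["y"]]))
})

test_that("ungapping any alignment row recovers the member sequence", {
  set.seed(15)
  base <- random_aa(50)
  mutate <- function(s) {
    v <- strsplit(s, "")[[1L]]
    i <- sample(length(v), 5)
    v[i] <- sample(c("A", "G", "S"), 5, replace = TRUE)
    paste(v[-sample(length(v), 2)], collapse = "")
  }
  members <- c(m1 = base, m2 = mutate(base), m3 = mutate(base))
  prof <- align_group(members)
  expect_setequal(prof$member_ids, names(members))
  for (id in names(members))
    expect_equal(gsub("-", "", prof$alignment[[id]], fixed = TRUE),
                 members[[id]])
  expect_equal(length(unique(nchar(prof$alignment))), 1L)
})

test_that("a group of fewer than two members is rejected", {
  expect_error(align_group(c(only = "MKVA")), "at least 2")
})

test_that("profile search finds the profile's source sequence on top", {
  set.seed(21)
  s <- random_aa(80)
  prof <- align_group(c(c1 = s, c2 = s))
  db <- c(X = s, Y = random_aa(80))
  hits <- profile_search(prof, db)
  expect_equal(hits$subject_id[1L], "X")
  # database sequences that are profile members are excluded
  hits2 <- profile_search(prof, c(c1 = s, Z = random_aa(80)))
  expect_false("c1" %in% hits2$subject_id)
})

test_that("profile search on an alphabet-disjoint database reports nothing strong", {
  prof <- align_group(c(a = strrep("W", 40), b = strrep("W", 40)))
  hits <- profile_search(prof, c(D = strrep("P", 60)), min_bitscore = 10)
  expect_equal(nrow(hits), 0L)
})

test_that("hmmer backend agrees with the internal backend on planted homology", {
  be_h <- mip_backend("hmmer")
  be_i <- mip_backend("internal")
  sim <- simulate_proteome(n_ancestors = 3, n_decoys_per_class = 2,
                           seed = 8, family_size = 0)
  p <- sim$proteome
  tr <- sim$truth$planted
  anc <- p[unique(tr$ancestor_id)]
  for (k in seq_len(nrow(tr))) {
    q <- p[tr$mip_id[k]]
    hi <- pairwise_search(q, anc, be_i, min_bitscore = 30)
    hh <- pairwise_search(q, anc, be_h, min_bitscore = 30)
    expect_true(tr$ancestor_id[k] %in% hi$subject_id)
    expect_true(tr$ancestor_id[k] %in% hh$subject_id)
  }
})

test_that("hmmer profile route recovers the ancestor of a homolog pair", {
  sim <- simulate_proteome(n_ancestors = 3, n_decoys_per_class = 2,
                           seed = 8, family_size = 0)
  p <- sim$proteome
  tr <- sim$truth$planted
  sib <- tr[tr$ancestor_id == "ANC003", ]   # every third ancestor has 2 copies
  expect_equal(nrow(sib), 2L)
  be <- mip_backend("hmmer")
  prof <- align_group(p[sib$mip_id], be)
  hits <- profile_search(prof, p[unique(tr$ancestor_id)], be)
  expect_true("ANC003" %in% hits$subject_id)
})
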