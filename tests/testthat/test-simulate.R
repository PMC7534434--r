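test_that("a fixed seed reproduces the fixture byte for byte", {
  s1 <- simulate_proteome(n_ancestors = 10, n_decoys_per_class = 3,
                          seed = 42)
  s2 <- simulate_proteome(n_ancestors = 10, n_decoys_per_class = 3,
                          seed = 42)
  expect_identical(s1$proteome$seqs, s2$proteome$seqs)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(s1, d1); write_fixture(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(simulate_proteome(n_ancestors = 2, seed = 9,
                                           n_decoys_per_class = 1,
                                           family_size = 0))
  expect_identical(rnorm(3), before)
})

test_that("every planted candidate aligns to its ancestor above the gate", {
  sim <- simulate_proteome(n_ancestors = 6, n_decoys_per_class = 3, seed = 19)
  p <- sim$proteome
  tr <- sim$truth$planted
  for (k in seq_len(nrow(tr))) {
    h <- pairwise_search(p[tr$mip_id[k]], p[tr$ancestor_id[k]],
                         min_bitscore = 30)
    expect_equal(nrow(h), 1L, info = tr$mip_id[k])
  }
})

test_that("truth-table coverage equals the length ratio to machine precision", {
  sim <- simulate_proteome(n_ancestors = 5, n_decoys_per_class = 2, seed = 23)
  len <- protein_lengths(sim$proteome)
  tr <- sim$truth$planted
  expect_equal(tr$expected_coverage,
               unname(len[tr$mip_id] / len[tr$ancestor_id]),
               tolerance = 1e-9)
  expect_true(all(tr$expected_coverage > 0 & tr$expected_coverage < 1))
})

test_that("planted candidates are unstable, decoys stable, classes complete", {
  sim <- simulate_proteome(n_ancestors = 6, n_decoys_per_class = 4, seed = 37)
  p <- sim$proteome
  tr <- sim$truth$planted
  expect_true(all(instability_index(p$seqs[tr$mip_id]) >= 70))
  dec <- sim$truth$decoys
  expect_setequal(unique(dec$decoy_class),
                  c("small_unrelated", "large_single_domain", "existence5",
                    "big_family_member"))
  dsu <- dec$id[dec$decoy_class == "small_unrelated"]
  expect_true(all(instability_index(p$seqs[dsu]) <= 40))
  expect_true(all(p$existence[dec$id[dec$decoy_class == "existence5"]] == 5L))
  fam <- dec$id[dec$decoy_class == "big_family_member"]
  expect_gte(length(fam), 11L)
  # family members are mutually homologous far above the clustering gate
  h <- pairwise_search(p[fam[1L]], p[fam[-1L]], min_bitscore = 30)
  expect_equal(nrow(h), length(fam) - 1L)
  # single-domain decoys carry exactly one Domain entry and exceed the
  # size boundary
  dld <- dec$id[dec$decoy_class == "large_single_domain"]
  expect_true(all(protein_lengths(p)[dld] > 150))
  expect_true(all(vapply(p$interpro[dld], nrow, integer(1)) == 1L))
})

test_that("planted candidate annotations mirror the source domain", {
  sim <- simulate_proteome(n_ancestors = 4, n_decoys_per_class = 2, seed = 41)
  p <- sim$proteome
  tr <- sim$truth$planted
  for (k in seq_len(nrow(tr))) {
    mip_ipr <- p$interpro[[tr$mip_id[k]]]
    expect_equal(nrow(mip_ipr), 1L)
    expect_true(mip_ipr$entry_id %in%
                  p$interpro[[tr$ancestor_id[k]]]$entry_id)
  }
  # ancestors are multidomain
  expect_true(all(vapply(p$interpro[unique(tr$ancestor_id)], nrow,
                         integer(1)) >= 2L))
})

test_that("fixture files on disk feed straight back into the pipeline", {
  sim <- simulate_proteome(n_ancestors = 3, n_decoys_per_class = 2, seed = 55)
  d <- withr::local_tempdir()
  write_fixture(sim, d)
  p <- read_proteome(file.path(d, "proteome.fasta"))
  p <- read_annotations(file.path(d, "annotations.tsv"), p)
  expect_identical(p$seqs, sim$proteome$seqs)
  expect_identical(p$existence, sim$proteome$existence)
})

test_that("simulated expression reproduces the requested correlation on average", {
  pairs <- data.frame(mip_id = sprintf("M%03d", 1:500),
                      target_id = sprintf("T%03d", 1:500),
                      stringsAsFactors = FALSE)
  expr <- simulate_expression(pairs, target_r = 0.95, n_samples = 10,
                              seed = 61)
  expect_true(all(expr >= 0))
  rs <- vapply(seq_len(nrow(pairs)), function(k)
    stats::cor(expr[pairs$mip_id[k], ], expr[pairs$target_id[k], ]),
    numeric(1))
  expect_lt(abs(mean(rs) - 0.95), 0.05)
  # fixed seed: identical matrix
  expr2 <- simulate_expression(pairs, target_r = 0.95, n_samples = 10,
                               seed = 61)
  expect_identical(expr, expr2)
})

test_that("ortholog simulation plants conserved copies where the truth says", {
  sim <- simulate_proteome(n_ancestors = 4, n_decoys_per_class = 2, seed = 12,
                           family_size = 0)
  orth <- simulate_orthologs(sim, n_species = 4, seed = 12)
  expect_length(orth$proteomes, 4L)
  truth <- orth$truth
  for (k in seq_len(nrow(truth))) {
    m <- truth$mip_id[k]
    present <- vapply(names(orth$proteomes), function(sp)
      any(grepl(paste0("_", m, "$"), protein_ids(orth$proteomes[[sp]]))),
      logical(1))
    expect_equal(sum(present), truth$n_species[k], info = m)
  }
})
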