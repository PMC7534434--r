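test_that("perfect linear relations give r of +/-1 with vanishing p", {
  x <- c(1, 2, 4, 7, 11, 16, 18, 20, 23, 30)
  up <- pearson_test(x, 2 * x + 1)
  expect_equal(up$r, 1.0, tolerance = 1e-12)
  expect_lt(up$p_value, 1e-12)
  down <- pearson_test(x, -x)
  expect_equal(down$r, -1.0, tolerance = 1e-12)
})

test_that("correlation is affine-invariant and flips sign with the slope", {
  set.seed(88)
  x <- rnorm(10); y <- rnorm(10)
  base <- pearson_test(x, y)
  shifted <- pearson_test(x, 3 * y + 7)
  flipped <- pearson_test(x, -2 * y + 1)
  expect_equal(base$r, shifted$r, tolerance = 1e-12)
  expect_equal(base$r, -flipped$r, tolerance = 1e-12)
  expect_equal(base$p_value, flipped$p_value, tolerance = 1e-12)
})

test_that("t-approximation p-value matches a permutation p-value", {
  set.seed(71)
  n <- 8
  for (k in 1:3) {
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- pearson_test(x, y)
    r_obs <- abs(got$r)
    perm <- replicate(20000, abs(stats::cor(x, sample(y))))
    p_perm <- mean(perm >= r_obs - 1e-12)
    # t-null and permutation-null differ slightly at n = 8; agreement is
    # asserted to within that approximation error plus Monte-Carlo noise
    expect_lt(abs(got$p_value - p_perm), 0.03)
  }
})

test_that("zero-variance profiles are flagged undefined, not errors", {
  r <- pearson_test(rep(3, 10), rnorm(10))
  expect_true(is.na(r$r))
  expect_equal(r$reason, "zero variance")
  expr <- rbind(M1 = rep(5, 10), T1 = rnorm(10))
  res <- significant_pairs(data.frame(mip_id = "M1", target_id = "T1"), expr)
  expect_false(res$significant)
  expect_equal(res$reason, "zero variance")
})

test_that("significance needs both |r| strictly above 0.7 and p strictly below 0.01", {
  # construct profiles whose sample correlation is exactly the requested r
  make_pair <- function(r, n = 10) {
    set.seed(99)
    x <- scale(rnorm(n))[, 1]
    z <- stats::residuals(stats::lm(rnorm(n) ~ x))
    z <- scale(z)[, 1]
    y <- r * x + sqrt(1 - r^2) * z
    rbind(M = 100 + 10 * x, T = 100 + 10 * y)
  }
  # n = 14 so that r just above 0.7 also clears p < 0.01 and the r
  # boundary is tested in isolation
  expr70 <- make_pair(0.70, n = 14)
  res70 <- significant_pairs(data.frame(mip_id = "M", target_id = "T"),
                             expr70)
  expect_equal(res70$r, 0.70, tolerance = 1e-9)
  expect_lt(res70$p, 0.01)
  expect_false(res70$significant)          # boundary excluded
  res71 <- significant_pairs(data.frame(mip_id = "M", target_id = "T"),
                             make_pair(0.71, n = 14))
  expect_true(res71$significant)
  resneg <- significant_pairs(data.frame(mip_id = "M", target_id = "T"),
                              make_pair(-0.9))
  expect_true(resneg$significant)          # negative co-regulation counts
  # strong r with too small n: p fails, pair not significant
  small <- make_pair(0.95, n = 4)
  ress <- significant_pairs(data.frame(mip_id = "M", target_id = "T"), small)
  expect_gt(ress$p, 0.01)
  expect_false(ress$significant)
})

test_that("pairs with ids missing from the matrix are skipped with a warning", {
  expr <- rbind(M1 = rnorm(10), T1 = rnorm(10))
  pairs <- data.frame(mip_id = c("M1", "M2"), target_id = c("T1", "T9"))
  expect_warning(res <- significant_pairs(pairs, expr), "skipped")
  expect_equal(nrow(res), 1L)
})

test_that("an impossible correlation threshold flags nothing", {
  sim_pairs <- data.frame(mip_id = sprintf("M%02d", 1:20),
                          target_id = sprintf("T%02d", 1:20))
  expr <- simulate_expression(sim_pairs, target_r = 0.9, seed = 31)
  res <- significant_pairs(sim_pairs, expr, r_threshold = 1.0)
  expect_false(any(res$significant))
})

test_that("keyword annotation joins both sides and tallies frequencies", {
  res <- data.frame(mip_id = c("M1", "M2"), target_id = c("T1", "T2"),
                    n = 10L, r = c(0.9, 0.8), p = c(0.001, 0.002),
                    significant = TRUE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  kw <- data.frame(id = c("T1", "T2", "M1"),
                   keywords = c("salt stress;root", "root;growth", "dwarf"),
                   stringsAsFactors = FALSE)
  ann <- annotate_pairs(res, kw)
  expect_equal(ann$target_keywords, c("salt stress;root", "root;growth"))
  expect_equal(ann$mip_keywords, c("dwarf", ""))   # unknown id: empty
  freq <- keyword_frequency(ann)
  expect_equal(freq$count[freq$keyword == "root"], 2L)
  expect_equal(freq$count[freq$keyword == "salt stress"], 1L)
})

test_that("expression TSV reading checks ids and finiteness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tt1\tt2\tt3", "G1\t1\t2\t3", "G2\t4\t5\t6"), f)
  m <- read_expression(f)
  expect_equal(rownames(m), c("G1", "G2"))
  expect_equal(unname(m["G2", ]), c(4, 5, 6))
  writeLines(c("gene_id\tt1", "G1\t1", "G1\t2"), f)
  expect_error(read_expression(f), "duplicate")
})
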