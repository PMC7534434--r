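# Independent alignment oracles, deliberately written with different
# recurrences than the package's compiled aligner.

blosum50 <- local({
  e <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = e)
  get("BLOSUM50", envir = e)
})

internal_bits_per_raw <- 0.232 / log(2)

# score an explicit gapped alignment (two equal-length rows) under affine
# gap costs: a gap run of length g costs open + g * extend
score_gapped <- function(ra, rb, sub = blosum50, open = 10, extend = 1) {
  a <- strsplit(ra, "")[[1L]]
  b <- strsplit(rb, "")[[1L]]
  s <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" && b[k] == "-") stop("double gap column")
    if (a[k] == "-") {
      s <- s - extend - if (in_gap_a) 0 else open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (b[k] == "-") {
      s <- s - extend - if (in_gap_b) 0 else open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      s <- s + sub[a[k], b[k]]
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  s
}

# exhaustive recursion over every global alignment of a vs b (tiny inputs
# only); returns the best affine-gap score
enumerate_global <- function(a, b, sub = blosum50, open = 10, extend = 1) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      v <- sub[av[i], bv[j]] + rec(i + 1L, j + 1L, "m")
      best <- max(best, v)
    }
    if (i <= length(av)) {
      v <- -extend - (if (last == "x") 0 else open) + rec(i + 1L, j, "x")
      best <- max(best, v)
    }
    if (j <= length(bv)) {
      v <- -extend - (if (last == "y") 0 else open) + rec(i, j + 1L, "y")
      best <- max(best, v)
    }
    best
  }
  rec(1L, 1L, "m")
}

# brute-force optimal local score: maximum over all substring pairs of the
# exhaustive global score (0 when nothing scores positively)
brute_local_enum <- function(a, b, sub = blosum50, open = 10, extend = 1) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      v <- enumerate_global(substr(a, i1, i2), substr(b, j1, j2),
                            sub, open, extend)
      if (v > best) best <- v
    }
  best
}

# prefix-alignment oracle for medium inputs: for every start pair, a plain
# R forward recursion over prefix alignments (no zero floor), maximised
# over all end cells
oracle_local_dp <- function(a, b, sub = blosum50, open = 10, extend = 1) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  best <- 0
  for (i0 in seq_along(av)) for (j0 in seq_along(bv)) {
    n <- length(av) - i0 + 1L; m <- length(bv) - j0 + 1L
    M <- matrix(-Inf, n + 1L, m + 1L)
    X <- matrix(-Inf, n + 1L, m + 1L)
    Y <- matrix(-Inf, n + 1L, m + 1L)
    M[1L, 1L] <- 0
    for (i in seq_len(n + 1L)) for (j in seq_len(m + 1L)) {
      if (i > 1L && j > 1L) {
        sc <- sub[av[i0 + i - 2L], bv[j0 + j - 2L]]
        M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                       Y[i - 1L, j - 1L]) + sc
      }
      if (i > 1L)
        X[i, j] <- max(M[i - 1L, j] - open - extend, X[i - 1L, j] - extend)
      if (j > 1L)
        Y[i, j] <- max(M[i, j - 1L] - open - extend, Y[i, j - 1L] - extend)
    }
    best <- max(best, max(M[-1L, -1L]))
  }
  best
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                      "I", "K", "L", "M", "N", "P", "Q",
                                      "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
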