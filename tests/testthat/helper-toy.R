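# Hand-built toy proteome exercising every filter boundary, paired with a
# fixed-table backend that injects exact bitscores.

aa_filler <- function(n) {
  pat <- strrep("ACDEFGHIKLMNPQRSTVWY", ceiling(n / 20))
  substr(pat, 1L, n)
}

toy_proteome <- function() {
  lens <- c(EX4 = 100L, EX5 = 100L, L150 = 150L, L151 = 151L,
            B1 = 100L, B2 = 100L, B3 = 100L, A = 100L,
            T9 = 400L, T10 = 400L, T120 = 400L, T121 = 400L,
            TS = 400L, TM39 = 189L, TM40 = 190L)
  seqs <- vapply(lens, aa_filler, character(1))
  two_dom <- function(i) data.frame(
    entry_id = sprintf("IPR%05d", c(i, i + 1L)),
    entry_type = "Domain", stringsAsFactors = FALSE)
  proteome(
    seqs,
    existence = c(EX4 = 4L, EX5 = 5L),
    interpro = list(
      T9 = two_dom(10L), T10 = two_dom(20L), T120 = two_dom(30L),
      T121 = two_dom(40L), TM39 = two_dom(50L), TM40 = two_dom(60L),
      L151 = two_dom(70L),
      # single annotated Domain: removed wherever it appears as a target
      TS = data.frame(entry_id = "IPR00099", entry_type = "Domain",
                      stringsAsFactors = FALSE)),
    source_label = "toy")
}

toy_backend <- function() {
  table_backend(data.frame(
    query_id = c("B1", "B2",
                 "B2", "B2", "B2", "B2", "B2",
                 "A", "A",
                 "L150", "L150",
                 "EX5"),
    subject_id = c("B2", "B3",
                   "T9", "T10", "T120", "T121", "TS",
                   "L151", "TS",
                   "TM39", "TM40",
                   "T10"),
    bitscore = c(29.9, 30.0,
                 9.9, 10.0, 120.0, 120.1, 60.0,
                 15.0, 80.0,
                 50.0, 50.0,
                 60.0),
    stringsAsFactors = FALSE))
}

# expected survivors of the toy cascade, per the closed boundary semantics
toy_expected <- list(
  A = "L151",                 # 15 bits in window; TS removed (single domain)
  B2 = c("T120", "T10"),      # window endpoints kept, 9.9/120.1 dropped
  L150 = "TM40"               # margin 40 kept, margin 39 dropped
)

new_group_for_test <- function(seed_id) {
  g <- list(seed_id = seed_id, homolog_ids = character(0),
            single_copy = TRUE,
            target_hits = data.frame(query_id = character(0),
                                     subject_id = character(0),
                                     bitscore = numeric(0),
                                     stringsAsFactors = FALSE))
  class(g) <- "candidate_group"
  g
}

# a candidate group with a prescribed number of homologs
group_with_homologs <- function(n, seed_id = "G") {
  g <- list(seed_id = seed_id,
            homolog_ids = if (n > 0) sprintf("H%02d", seq_len(n))
                          else character(0),
            single_copy = n == 0L,
            target_hits = data.frame(
              query_id = seed_id, subject_id = "T", bitscore = 50,
              q_start = 1L, q_end = 10L, s_start = 1L, s_end = 10L,
              stringsAsFactors = FALSE))
  class(g) <- "candidate_group"
  g
}
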