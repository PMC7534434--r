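#' Homology search backends
#'
#' The pipeline needs three homology primitives: pairwise sequence search,
#' multiple alignment of a homolog group, and profile search of that group
#' against a database. Two interchangeable backends provide them:
#'
#' * `"internal"` (default): an affine-gap Smith-Waterman / Needleman-Wunsch
#'   aligner compiled into the package, scoring with BLOSUM50 (gap open 10,
#'   gap extend 1, the conventional penalties for that matrix). Raw scores
#'   are converted to bits as `raw * lambda / ln 2` with a fixed nominal
#'   `lambda = 0.232` for BLOSUM50. This conversion is an approximation to
#'   the bitscores of a probabilistic search tool, adequate for the
#'   pipeline's gates; it is exactly reproducible with no external binaries.
#'   Multiple alignment uses a center-star progressive strategy and profile
#'   search scores the database against the profile's column consensus.
#' * `"hmmer"`: shells out to `phmmer`, `hmmbuild` and `hmmsearch`
#'   (gap open/extend probabilities 0.1/0.1, BLOSUM50, matching the printed
#'   production parameters) and to `mafft` for the multiple alignment step.
#'   Requires those programs on `PATH`.
#'
#' @param type `"internal"` or `"hmmer"`.
#' @param gap_open,gap_extend affine gap penalties of the internal aligner;
#'   a gap of length g costs `gap_open + g * gap_extend`.
#' @param matrix substitution matrix name (as shipped by `Biostrings`).
#' @param lambda nominal Karlin-Altschul scale used for the raw-score to
#'   bits conversion of the internal backend.
#' @return A backend object used by [pairwise_search()], [align_group()]
#'   and [profile_search()].
#' @export
mip_backend <- function(type = c("internal", "hmmer"),
                        gap_open = 10, gap_extend = 1,
                        matrix = "BLOSUM50", lambda = 0.232) {
  type <- match.arg(type)
  stopifnot(gap_open >= 0, gap_extend > 0, lambda > 0)
  structure(list(type = type, gap_open = gap_open, gap_extend = gap_extend,
                 matrix = matrix, lambda = lambda),
            class = c(paste0(type, "_backend"), "mip_backend"))
}

#' Fixed-table backend for contract testing
#'
#' A backend whose pairwise "search" simply looks up a prescribed hit table,
#' so filter-boundary behaviour (e.g. a hit at exactly 30.0 bits) can be
#' exercised without constructing sequences with those scores. Profile
#' searches return the rows of the profile's first member (its seed).
#'
#' @param hits data.frame with columns `query_id`, `subject_id`, `bitscore`
#'   (spans optional).
#' @return A backend object.
#' @export
table_backend <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("query_id", "subject_id", "bitscore") %in% names(hits)))
  for (col in c("q_start", "q_end", "s_start", "s_end"))
    if (is.null(hits[[col]])) hits[[col]] <- NA_integer_
  structure(list(hits = hits), class = c("table_backend", "mip_backend"))
}

as_seq_vector <- function(x) {
  if (inherits(x, "proteome")) return(x$seqs)
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    return(toupper(x))
  }
  stop("expected a proteome or a named character vector")
}

sub_matrix <- function(backend) {
  e <- new.env()
  utils::data(list = backend$matrix, package = "Biostrings", envir = e)
  get(backend$matrix, envir = e)
}

# residues without a matrix column are scored as X
canon_for_matrix <- function(s) chartr("UOJ", "XXX", s)

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             bitscore = numeric(0), q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             stringsAsFactors = FALSE)
}

sort_hits <- function(hits) {
  hits[order(-hits$bitscore, hits$query_id, hits$subject_id,
             method = "radix"), , drop = FALSE]
}

#' Pairwise homology search
#'
#' Searches every query against every database sequence and reports scored
#' hits. Self-hits (identical identifiers) are excluded. Hits are sorted by
#' descending bitscore, ties broken by ascending query then subject
#' identifier, and the ordering is deterministic for a given backend and
#' byte-identical inputs.
#'
#' @param queries,database [proteome] objects or named character vectors.
#' @param backend a [mip_backend()] (or [table_backend()]) object.
#' @param min_bitscore hits below this value are dropped (0 reports all
#'   positive-scoring hits).
#' @return data.frame with columns `query_id`, `subject_id`, `bitscore`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (1-based inclusive spans).
#' @export
pairwise_search <- function(queries, database, backend = mip_backend(),
                            min_bitscore = 0) {
  q <- as_seq_vector(queries)
  d <- as_seq_vector(database)
  if (length(q) == 0L || length(d) == 0L) return(empty_hits())
  hits <- backend_pairwise(backend, q, d)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  hits <- hits[hits$bitscore >= min_bitscore & hits$bitscore > 0, ,
               drop = FALSE]
  sort_hits(hits)
}

backend_pairwise <- function(backend, q, d)
  UseMethod("backend_pairwise")

#' @export
backend_pairwise.internal_backend <- function(backend, q, d) {
  sub <- sub_matrix(backend)
  bits_per_raw <- backend$lambda / log(2)
  qc <- canon_for_matrix(q)
  dc <- canon_for_matrix(d)
  cap <- length(q) * length(d)
  qid <- character(cap); sid <- character(cap); bits <- numeric(cap)
  span <- matrix(0L, nrow = cap, ncol = 4L)
  n <- 0L
  for (qi in seq_along(q)) {
    for (di in seq_along(d)) {
      if (names(q)[qi] == names(d)[di]) next
      al <- .sw_align(qc[[qi]], dc[[di]], sub,
                      backend$gap_open, backend$gap_extend)
      if (al$score <= 0) next
      n <- n + 1L
      qid[n] <- names(q)[qi]; sid[n] <- names(d)[di]
      bits[n] <- al$score * bits_per_raw
      span[n, ] <- c(al$q_start, al$q_end, al$s_start, al$s_end)
    }
  }
  if (n == 0L) return(empty_hits())
  k <- seq_len(n)
  data.frame(query_id = qid[k], subject_id = sid[k], bitscore = bits[k],
             q_start = span[k, 1L], q_end = span[k, 2L],
             s_start = span[k, 3L], s_end = span[k, 4L],
             stringsAsFactors = FALSE)
}

#' @export
backend_pairwise.table_backend <- function(backend, q, d) {
  h <- backend$hits
  h[h$query_id %in% names(q) & h$subject_id %in% names(d), , drop = FALSE]
}

#' Align a group of homologous proteins
#'
#' Builds a multiple sequence alignment (the internal backend uses a
#' center-star strategy around the longest member) and the derived profile
#' used by [profile_search()]. Ungapping any alignment row recovers the
#' member's original sequence.
#'
#' @param members [proteome] or named character vector with at least two
#'   sequences.
#' @inheritParams pairwise_search
#' @return An object of class `homology_profile` with fields `member_ids`,
#'   `alignment` (named character, equal-length gapped rows) and
#'   `consensus`.
#' @export
align_group <- function(members, backend = mip_backend()) {
  m <- as_seq_vector(members)
  if (length(m) < 2L) stop("a homolog group needs at least 2 members")
  aln <- backend_msa(backend, m)
  structure(list(member_ids = names(m), alignment = aln,
                 consensus = consensus_sequence(aln)),
            class = "homology_profile")
}

backend_msa <- function(backend, m) UseMethod("backend_msa")

#' @export
backend_msa.internal_backend <- function(backend, m) {
  sub <- sub_matrix(backend)
  # center-star: align every member to the longest sequence and merge the
  # center gaps pairwise
  ord <- order(-nchar(m), names(m), method = "radix")
  center <- m[[ord[1L]]]
  rows <- list()
  rows[[names(m)[ord[1L]]]] <- center
  for (k in ord[-1L]) {
    al <- .nw_align(canon_for_matrix(m[[k]]), canon_for_matrix(center), sub,
                    backend$gap_open, backend$gap_extend)
    # restore original residues (canonicalisation only affects scoring)
    arow <- restore_residues(al$aligned_a, m[[k]])
    crow <- restore_residues(al$aligned_b, center)
    rows <- merge_into_star(rows, names(m)[ord[1L]], crow, names(m)[k], arow)
  }
  unlist(rows)[names(m)]
}

#' @export
backend_msa.table_backend <- function(backend, m) {
  # pad to equal length; the table backend never inspects alignments
  w <- max(nchar(m))
  vapply(m, function(s) paste0(s, strrep("-", w - nchar(s))), character(1))
}

restore_residues <- function(gapped, original) {
  res <- strsplit(gapped, "")[[1L]]
  res[res != "-"] <- strsplit(original, "")[[1L]]
  paste(res, collapse = "")
}

# merge a new (center, member) pairwise alignment into the running MSA,
# propagating any new center gaps to all existing rows
merge_into_star <- function(rows, center_id, new_center_row, member_id,
                            member_row) {
  old_center <- strsplit(rows[[center_id]], "")[[1L]]
  new_center <- strsplit(new_center_row, "")[[1L]]
  member <- strsplit(member_row, "")[[1L]]
  oi <- 1L; ni <- 1L
  out_cols <- list()
  merged_member <- character(0)
  no <- length(old_center); nn <- length(new_center)
  col_old <- integer(0); col_new <- integer(0)
  while (oi <= no || ni <= nn) {
    old_gap <- oi <= no && old_center[oi] == "-"
    new_gap <- ni <= nn && new_center[ni] == "-"
    old_res <- oi <= no && !old_gap
    new_res <- ni <= nn && !new_gap
    if (old_res && new_res) { col_old <- c(col_old, oi); col_new <- c(col_new, ni); oi <- oi + 1L; ni <- ni + 1L }
    else if (old_gap) { col_old <- c(col_old, oi); col_new <- c(col_new, NA); oi <- oi + 1L }
    else if (new_gap) { col_old <- c(col_old, NA); col_new <- c(col_new, ni); ni <- ni + 1L }
    else break
  }
  take <- function(v, idx) ifelse(is.na(idx), "-", v[pmax(idx, 1L)])
  rows <- lapply(rows, function(r) {
    rc <- strsplit(r, "")[[1L]]
    paste(take(rc, col_old), collapse = "")
  })
  rows[[member_id]] <- paste(take(member, col_new), collapse = "")
  rows
}

# column-wise majority residue, ties broken alphabetically; all-gap columns
# are dropped
consensus_sequence <- function(aln) {
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  cons <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("")
    tab <- sort(table(col), decreasing = TRUE)
    cand <- names(tab)[tab == tab[1L]]
    sort(cand)[1L]
  })
  paste(cons, collapse = "")
}

#' Search a homolog-group profile against a database
#'
#' The internal backend scores the database against the profile's consensus
#' sequence with the same pairwise semantics as [pairwise_search()]; the
#' hmmer backend builds a profile HMM from the group alignment and runs
#' `hmmsearch`. Subjects that are themselves members of the profile are
#' excluded (the pipeline treats them as the candidate's homologs, not its
#' targets).
#'
#' @param profile a `homology_profile` from [align_group()].
#' @inheritParams pairwise_search
#' @return Hit data.frame as for [pairwise_search()], sorted by descending
#'   bitscore then ascending subject id.
#' @export
profile_search <- function(profile, database, backend = mip_backend(),
                           min_bitscore = 0) {
  stopifnot(inherits(profile, "homology_profile"))
  d <- as_seq_vector(database)
  d <- d[!names(d) %in% profile$member_ids]
  if (length(d) == 0L) return(empty_hits())
  hits <- backend_profile(backend, profile, d)
  hits <- hits[hits$bitscore >= min_bitscore & hits$bitscore > 0, ,
               drop = FALSE]
  sort_hits(hits)
}

backend_profile <- function(backend, profile, d) UseMethod("backend_profile")

#' @export
backend_profile.internal_backend <- function(backend, profile, d) {
  q <- setNames(profile$consensus, profile$member_ids[1L])
  hits <- backend_pairwise.internal_backend(backend, q, d)
  hits$query_id <- rep(profile$member_ids[1L], nrow(hits))
  hits
}

#' @export
backend_profile.table_backend <- function(backend, profile, d) {
  h <- backend$hits
  h[h$query_id == profile$member_ids[1L] & h$subject_id %in% names(d), ,
    drop = FALSE]
}
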