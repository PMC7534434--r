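# HMMER-suite production backend: phmmer for pairwise search, mafft for the
# group alignment, hmmbuild + hmmsearch for profile search. All exchange
# happens through FASTA/Stockholm temp files; bitscores are the full-sequence
# bitscores reported by the tools, spans the envelope of the best domain.

hmmer_check <- function(tool) {
  p <- Sys.which(tool)
  if (!nzchar(p))
    stop("backend binary '", tool, "' not found on PATH; use ",
         "mip_backend(\"internal\") (config key homology.backend) instead",
         call. = FALSE)
  p
}

write_temp_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), f)
  f
}

run_tool <- function(bin, args) {
  out <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop(basename(bin), " failed (exit ", status, "):\n",
         paste(utils::tail(out, 15L), collapse = "\n"), call. = FALSE)
  out
}

# --domtblout format: whitespace-separated, comment lines start with '#'.
parse_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  f <- strsplit(trimws(lines), "\\s+")
  df <- data.frame(
    subject_id = vapply(f, `[`, character(1), 1L),
    query_id = vapply(f, `[`, character(1), 4L),
    bitscore = as.numeric(vapply(f, `[`, character(1), 8L)),
    dom_score = as.numeric(vapply(f, `[`, character(1), 14L)),
    q_start = as.integer(vapply(f, `[`, character(1), 16L)),
    q_end = as.integer(vapply(f, `[`, character(1), 17L)),
    s_start = as.integer(vapply(f, `[`, character(1), 18L)),
    s_end = as.integer(vapply(f, `[`, character(1), 19L)),
    stringsAsFactors = FALSE)
  # keep the best-scoring domain row per (query, subject)
  df <- df[order(-df$dom_score), , drop = FALSE]
  df <- df[!duplicated(df[c("query_id", "subject_id")]), , drop = FALSE]
  df[c("query_id", "subject_id", "bitscore",
       "q_start", "q_end", "s_start", "s_end")]
}

#' @export
backend_pairwise.hmmer_backend <- function(backend, q, d) {
  phmmer <- hmmer_check("phmmer")
  dbf <- write_temp_fasta(d)
  on.exit(unlink(dbf), add = TRUE)
  out <- vector("list", length(q))
  for (qi in seq_along(q)) {
    qf <- write_temp_fasta(q[qi])
    tbl <- tempfile(fileext = ".domtbl")
    run_tool(phmmer, c("--popen", "0.1", "--pextend", "0.1",
                       "--mx", backend$matrix,
                       "-E", "1000", "--domE", "1000",
                       "--domtblout", shQuote(tbl), "-o", "/dev/null",
                       shQuote(qf), shQuote(dbf)))
    out[[qi]] <- parse_domtbl(tbl)
    unlink(c(qf, tbl))
  }
  do.call(rbind, out)
}

#' @export
backend_msa.hmmer_backend <- function(backend, m) {
  mafft <- hmmer_check("mafft")
  inf <- write_temp_fasta(m)
  on.exit(unlink(inf), add = TRUE)
  out <- run_tool(mafft, c("--auto", "--quiet", shQuote(inf)))
  # parse FASTA from stdout
  hdr <- grep("^>", out)
  ids <- sub("^>", "", out[hdr])
  ends <- c(hdr[-1L] - 1L, length(out))
  aln <- vapply(seq_along(hdr), function(k)
    paste(out[(hdr[k] + 1L):ends[k]], collapse = ""), character(1))
  setNames(toupper(aln), ids)[names(m)]
}

#' @export
backend_profile.hmmer_backend <- function(backend, profile, d) {
  hmmbuild <- hmmer_check("hmmbuild")
  hmmsearch <- hmmer_check("hmmsearch")
  alnf <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(profile$alignment), "\n", profile$alignment),
             alnf)
  hmmf <- tempfile(fileext = ".hmm")
  dbf <- write_temp_fasta(d)
  tbl <- tempfile(fileext = ".domtbl")
  on.exit(unlink(c(alnf, hmmf, dbf, tbl)), add = TRUE)
  run_tool(hmmbuild, c("--amino", shQuote(hmmf), shQuote(alnf)))
  run_tool(hmmsearch, c("-E", "1000", "--domE", "1000",
                        "--domtblout", shQuote(tbl), "-o", "/dev/null",
                        shQuote(hmmf), shQuote(dbf)))
  hits <- parse_domtbl(tbl)
  hits$query_id <- rep(profile$member_ids[1L], nrow(hits))
  hits
}
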