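#' Write the ranked pair table to TSV
#'
#' Columns: `mip_id`, `target_id`, `bitscore`, `mip_length`,
#' `target_length`, `coverage`, `instability_index`, `weight`, `score`,
#' `rank`, `percentile`, `single_copy_flag`. Rows are sorted by rank;
#' floating-point values are rendered with 6 significant digits so reruns
#' are byte-identical.
#'
#' @param pairs ranked pairs from [rank_pairs()] (or a `mip_screen`'s
#'   `$pairs`).
#' @param out_path output path.
#' @return Invisibly, `out_path`.
#' @export
write_pairs <- function(pairs, out_path) {
  cols <- c("mip_id", "target_id", "bitscore", "mip_length", "target_length",
            "coverage", "instability_index", "weight", "score", "rank",
            "percentile", "single_copy_flag")
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$rank), , drop = FALSE]
    num <- function(v) formatC(signif(v, 6), format = "g", digits = 6)
    body <- paste(pairs$mip_id, pairs$target_id, num(pairs$bitscore),
                  pairs$mip_length, pairs$target_length, num(pairs$coverage),
                  num(pairs$instability_index), num(pairs$weight),
                  num(pairs$score), pairs$rank, pairs$percentile,
                  as.integer(pairs$single_copy), sep = "\t")
  } else body <- character(0)
  con <- file(out_path, "w")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), body), con)
  invisible(out_path)
}

#' Read a pair table written by [write_pairs()]
#'
#' @param path path to the TSV.
#' @return data.frame mirroring the written columns (the single-copy flag
#'   is returned as logical `single_copy`).
#' @export
read_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$single_copy <- df$single_copy_flag == 1L
  df$single_copy_flag <- NULL
  df
}

#' GO terms of the best targets of each microProtein
#'
#' For each microProtein in `pairs`, takes its up-to-`top_n_targets`
#' highest-scoring targets and concatenates their GO identifiers
#' (duplicates preserved - the output feeds term-enrichment tools that
#' weight by frequency). MicroProteins are visited in ascending identifier
#' order, their targets in descending score order, so the output is
#' deterministic.
#'
#' @param pairs scored (and typically ranked) pair table.
#' @param x the annotated [proteome] carrying GO terms.
#' @param top_n_targets targets considered per microProtein.
#' @return Character vector of GO identifiers (possibly with duplicates).
#' @export
extract_target_go <- function(pairs, x, top_n_targets = 10L) {
  if (nrow(pairs) == 0L) return(character(0))
  out <- character(0)
  for (mip in sort(unique(pairs$mip_id))) {
    sub <- pairs[pairs$mip_id == mip, , drop = FALSE]
    sub <- sub[order(-sub$score, sub$target_id, method = "radix"), ,
               drop = FALSE]
    tids <- utils::head(sub$target_id, top_n_targets)
    out <- c(out, unlist(lapply(tids, function(id) x$go[[id]]),
                         use.names = FALSE))
  }
  out
}

#' Write conservation records to TSV
#'
#' One row per conserved microProtein: its id, the best bitscore per other
#' species, the number of species in which it is conserved, and its best
#' target pair (id and score) when supplied.
#'
#' @param records result of [conserved_candidates()].
#' @param out_path output path.
#' @return Invisibly, `out_path`.
#' @export
write_conservation <- function(records, out_path) {
  num <- function(v) ifelse(is.na(v), "NA",
                            formatC(signif(v, 6), format = "g", digits = 6))
  df <- records
  for (col in names(df))
    if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
      df[[col]] <- num(df[[col]])
  write.table(df, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_path)
}
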