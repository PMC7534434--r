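#' Read a genes-by-samples expression matrix from TSV
#'
#' First column gene id, remaining columns one per sample (e.g. ten
#' anatomical tissues); header row required; values non-negative reals
#' (counts or TPM).
#'
#' @param path path to the TSV.
#' @return Numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate gene id(s) in expression matrix")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite values in expression matrix")
  m
}

#' Pearson correlation with a two-sided t-test
#'
#' Sample Pearson correlation of two profiles with the conventional
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom (as implemented by [stats::cor.test()]). A
#' zero-variance profile makes the coefficient undefined; the result is
#' then flagged rather than an error thrown so such pairs can be reported
#' non-significant with a reason.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return List with `r`, `p_value`, `n`, and `reason` (`NA` unless the
#'   test was undefined).
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("profiles differ in length")
  if (n < 3L) stop("need at least 3 samples")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n,
                reason = "zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n,
       reason = NA_character_)
}

#' Test microProtein-target pairs for significant co-expression
#'
#' One Pearson test per pair across the expression samples; a pair is
#' significant when `|r| > r_threshold` and `p < p_threshold` (both strict;
#' positive and negative co-regulation both count). Pairs whose ids are
#' missing from the matrix are skipped with a warning; zero-variance pairs
#' are reported non-significant with a reason.
#'
#' @param pairs data.frame with `mip_id` and `target_id` columns (extra
#'   columns ignored).
#' @param expr expression matrix from [read_expression()] (genes in rows).
#' @param r_threshold absolute-correlation threshold (strict).
#' @param p_threshold p-value threshold (strict).
#' @param log2p1 if `TRUE`, correlate `log2(value + 1)` instead of the raw
#'   values.
#' @return data.frame with `mip_id`, `target_id`, `n`, `r`, `p`,
#'   `significant`, `reason`.
#' @export
significant_pairs <- function(pairs, expr, r_threshold = 0.7,
                              p_threshold = 0.01, log2p1 = FALSE) {
  if (log2p1) expr <- log2(expr + 1)
  present <- pairs$mip_id %in% rownames(expr) &
    pairs$target_id %in% rownames(expr)
  if (any(!present))
    warning(sum(!present), " pair(s) with ids absent from the expression ",
            "matrix skipped", call. = FALSE)
  pairs <- pairs[present, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    t <- pearson_test(expr[pairs$mip_id[k], ], expr[pairs$target_id[k], ])
    data.frame(mip_id = pairs$mip_id[k], target_id = pairs$target_id[k],
               n = t$n, r = t$r, p = t$p_value,
               significant = !is.na(t$r) && abs(t$r) > r_threshold &&
                 t$p_value < p_threshold,
               reason = t$reason, stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(mip_id = character(0), target_id = character(0),
               n = integer(0), r = numeric(0), p = numeric(0),
               significant = logical(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach curated keywords to correlation results
#'
#' Joins a two-column keyword table (id, semicolon-joined keywords, e.g. a
#' curated rice gene-function table) onto both sides of each pair; missing
#' ids yield empty keyword strings.
#'
#' @param results data.frame from [significant_pairs()].
#' @param keyword_table data.frame with columns `id` and `keywords`
#'   (semicolon-joined), or a named character vector.
#' @return `results` with `mip_keywords` and `target_keywords` columns.
#' @export
annotate_pairs <- function(results, keyword_table) {
  if (is.data.frame(keyword_table))
    kw <- setNames(as.character(keyword_table$keywords), keyword_table$id)
  else kw <- keyword_table
  look <- function(ids) {
    v <- kw[ids]
    v[is.na(v)] <- ""
    unname(v)
  }
  results$mip_keywords <- look(results$mip_id)
  results$target_keywords <- look(results$target_id)
  results
}

#' Keyword frequency tally over annotated targets
#'
#' Splits the semicolon-joined target keywords of (typically significant)
#' annotated pairs and counts each keyword's occurrences, the tabular
#' form of a keyword-frequency summary.
#'
#' @param annotated data.frame from [annotate_pairs()].
#' @return data.frame with `keyword` and `count`, sorted by decreasing
#'   count then keyword.
#' @export
keyword_frequency <- function(annotated) {
  words <- unlist(strsplit(annotated$target_keywords, ";", fixed = TRUE))
  words <- words[nzchar(words)]
  if (!length(words))
    return(data.frame(keyword = character(0), count = integer(0)))
  tab <- table(words)
  out <- data.frame(keyword = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$keyword), , drop = FALSE]
}
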