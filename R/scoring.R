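#' Scoring parameters
#'
#' Numeric constants of the composite confidence score. The coverage weight
#' is the sigmoid `10 / (1 + exp(-k * (coverage * 100 - m)))` with `k = 0.1`
#' and `m = 50`, i.e. its midpoint (weight 5) sits at coverage 0.5 and its
#' range is the open interval (0, 10). The instability factor is
#' `1 / (1 + exp(-ii_slope * (II - ii_center)))` with midpoint at an
#' instability index of 70.
#'
#' The published score formula's first factor is typographically ambiguous;
#' the two defensible parses are available as explicit variants:
#' `"literal"` (default), in which the leading `1/bitscore` and `bitscore`
#' cancel so the score is `coverage * weight * instability_factor`, and
#' `"bitscore_weighted"`, which multiplies that product by the bitscore.
#'
#' @param k slope of the coverage-weight sigmoid (per coverage percentage
#'   point).
#' @param m midpoint of the coverage-weight sigmoid, in coverage percentage
#'   points.
#' @param ii_slope slope of the instability sigmoid (per instability-index
#'   unit).
#' @param ii_center midpoint of the instability sigmoid on the
#'   Guruprasad instability-index scale.
#' @param formula_variant `"literal"` or `"bitscore_weighted"`.
#' @return An object of class `score_params`.
#' @export
score_params <- function(k = 0.1, m = 50, ii_slope = 0.1, ii_center = 70.0,
                         formula_variant = c("literal", "bitscore_weighted")) {
  stopifnot(k > 0, ii_slope > 0)
  structure(list(k = k, m = m, ii_slope = ii_slope, ii_center = ii_center,
                 formula_variant = match.arg(formula_variant)),
            class = "score_params")
}

#' Protein instability index
#'
#' The dipeptide-weight instability index of Guruprasad, Reddy and Pandit:
#' `II = (10 / L) * sum(DIWV(x_i, x_{i+1}))` over all consecutive residue
#' pairs, with the published 20x20 dipeptide instability weight table.
#' Values above 40 conventionally predict an unstable protein in vitro.
#' Dipeptides containing a non-canonical residue (X, B, Z, U) contribute
#' weight 1.0.
#'
#' @param sequence amino-acid string(s); each must contain at least two
#'   canonical residues.
#' @return Numeric vector of instability indices.
#' @examples
#' instability_index("AAAAAAAAAA") # 9: nine A-A dipeptides of weight 1
#' @export
instability_index <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    res <- strsplit(s, "")[[1L]]
    L <- length(res)
    if (sum(res %in% .diwv_aas) < 2L)
      stop("instability index needs at least 2 canonical residues")
    if (L < 2L) stop("instability index needs at least 2 residues")
    a <- res[-L]; b <- res[-1L]
    known <- a %in% .diwv_aas & b %in% .diwv_aas
    w <- rep(1.0, L - 1L)
    w[known] <- .DIWV[cbind(a[known], b[known])]
    10 / L * sum(w)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Coverage of a target by a microProtein
#'
#' Defined as microProtein length divided by the identified target
#' (ancestor) length; after the length-margin filter this is always in
#' (0, 1).
#'
#' @param mip_length,target_length residue counts (positive).
#' @return `mip_length / target_length`.
#' @export
coverage <- function(mip_length, target_length) {
  if (any(mip_length <= 0) || any(target_length <= 0))
    stop("lengths must be positive")
  mip_length / target_length
}

#' Coverage weight sigmoid
#'
#' `10 / (1 + exp(-k * (coverage * 100 - m)))`: strictly increasing in
#' coverage with open range (0, 10) and value 5 at coverage `m / 100`.
#'
#' @param cov coverage ratio(s) in (0, 1].
#' @param params a [score_params()] object.
#' @return Numeric weight(s) in (0, 10).
#' @export
coverage_weight <- function(cov, params = score_params()) {
  10 / (1 + exp(-params$k * (cov * 100 - params$m)))
}

#' Instability sigmoid factor
#'
#' `1 / (1 + exp(-ii_slope * (II - ii_center)))`: strictly increasing in the
#' instability index with open range (0, 1) and value 0.5 at
#' `II = ii_center`.
#'
#' @param ii instability index value(s).
#' @inheritParams coverage_weight
#' @return Numeric factor(s) in (0, 1).
#' @export
instability_sigmoid <- function(ii, params = score_params()) {
  1 / (1 + exp(-params$ii_slope * (ii - params$ii_center)))
}

#' Composite pair score
#'
#' In the default `"literal"` variant the bitscore cancels and the score is
#' `coverage * coverage_weight(coverage) * instability_sigmoid(II)`; the
#' `"bitscore_weighted"` variant multiplies this product by the bitscore.
#'
#' @param bitscore homology bitscore of the pair (bits).
#' @param cov coverage ratio in (0, 1).
#' @param ii instability index of the microProtein sequence.
#' @inheritParams coverage_weight
#' @return Non-negative numeric score(s).
#' @export
score_pair <- function(bitscore, cov, ii, params = score_params()) {
  base <- cov * coverage_weight(cov, params) * instability_sigmoid(ii, params)
  switch(params$formula_variant,
         literal = base,
         bitscore_weighted = bitscore * base)
}

#' Rank scored microProtein-target pairs
#'
#' Sorts pairs by descending score (ties broken by ascending microProtein
#' then target identifier), assigns 1-based ranks, integer percentiles
#' `ceiling(100 * rank / N)`, and flags the high-confidence top fraction
#' (`rank <= ceiling(top_fraction * N)`).
#'
#' @param pairs data.frame of scored pairs with at least `mip_id`,
#'   `target_id` and `score` columns.
#' @param params a [pipeline_params()] object (supplies `top_fraction`).
#' @return The pairs with `rank`, `percentile` and `high_confidence`
#'   columns, sorted by rank.
#' @export
rank_pairs <- function(pairs, params = pipeline_params()) {
  if (nrow(pairs) == 0L) {
    pairs$rank <- integer(0); pairs$percentile <- integer(0)
    pairs$high_confidence <- logical(0)
    return(pairs)
  }
  ord <- order(-pairs$score, pairs$mip_id, pairs$target_id, method = "radix")
  pairs <- pairs[ord, , drop = FALSE]
  n <- nrow(pairs)
  pairs$rank <- seq_len(n)
  pairs$percentile <- as.integer(ceiling(100 * pairs$rank / n))
  pairs$high_confidence <- pairs$rank <= ceiling(params$top_fraction * n)
  rownames(pairs) <- NULL
  pairs
}

#' Select the high-confidence top fraction of ranked pairs
#'
#' @param pairs ranked pairs from [rank_pairs()].
#' @param top_fraction proportion of pairs to keep (default the screening
#'   convention of 0.10).
#' @return The top `ceiling(top_fraction * N)` pairs by rank.
#' @export
select_top_fraction <- function(pairs, top_fraction = 0.10) {
  if (nrow(pairs) == 0L) return(pairs)
  pairs[pairs$rank <= ceiling(top_fraction * nrow(pairs)), , drop = FALSE]
}
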