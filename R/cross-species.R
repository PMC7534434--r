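#' Cross-species conservation of candidate microProteins
#'
#' Searches each focal candidate against the full protein set of every
#' other proteome; a species counts as conserved when any hit reaches the
#' candidate homology gate (`params$min_cmip_bitscore`, 30 bits by default
#' - the only homology threshold the screening method states, reused here).
#' Candidates conserved in at least `min_species` other species are
#' returned. With `params$restrict_conservation_to_small` the search is
#' limited to the other species' proteins at or below the size boundary.
#'
#' @param focal_mips [proteome] (or named character vector) of candidate
#'   microProteins of the focal species.
#' @param other_proteomes list of [proteome] objects, named by species
#'   label.
#' @param min_species minimum number of other species with a conserved
#'   homolog.
#' @param params a [pipeline_params()] object.
#' @param backend a [mip_backend()] object.
#' @return data.frame with `mip_id`, one `best_bits_<species>` column per
#'   other proteome, and `n_species_conserved`, restricted to candidates
#'   meeting `min_species`.
#' @export
conserved_candidates <- function(focal_mips, other_proteomes,
                                 min_species = 3L,
                                 params = pipeline_params(),
                                 backend = mip_backend()) {
  if (length(other_proteomes) < min_species)
    stop("need at least ", min_species, " other proteomes, got ",
         length(other_proteomes))
  if (is.null(names(other_proteomes)) || any(!nzchar(names(other_proteomes))))
    names(other_proteomes) <- paste0("species", seq_along(other_proteomes))
  mips <- as_seq_vector(focal_mips)
  best <- matrix(0, nrow = length(mips), ncol = length(other_proteomes),
                 dimnames = list(names(mips), names(other_proteomes)))
  for (sp in names(other_proteomes)) {
    db <- other_proteomes[[sp]]
    if (params$restrict_conservation_to_small)
      db <- db[protein_lengths(db) <= params$size_boundary]
    hits <- pairwise_search(mips, db, backend)
    if (nrow(hits)) {
      agg <- tapply(hits$bitscore, hits$query_id, max)
      best[names(agg), sp] <- agg
    }
  }
  n_cons <- rowSums(best >= params$min_cmip_bitscore)
  out <- data.frame(mip_id = rownames(best), stringsAsFactors = FALSE)
  for (sp in colnames(best)) out[[paste0("best_bits_", sp)]] <- best[, sp]
  out$n_species_conserved <- as.integer(n_cons)
  out <- out[out$n_species_conserved >= min_species, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-scoring target pair of a microProtein
#'
#' @param mip_id candidate identifier.
#' @param pairs scored pair table.
#' @return The single row with maximal score for `mip_id` (ties broken by
#'   ascending target id).
#' @export
best_pair <- function(mip_id, pairs) {
  sub <- pairs[pairs$mip_id == mip_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no pairs for microProtein '", mip_id, "'")
  sub <- sub[order(-sub$score, sub$target_id, method = "radix"), ,
             drop = FALSE]
  sub[1L, , drop = FALSE]
}
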