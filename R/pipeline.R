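#' Pipeline parameters
#'
#' Every numeric knob of the screening cascade in one place, with the
#' published defaults. Boundary semantics are closed exactly as printed:
#' a candidate microProtein is a protein of length `<= size_boundary`;
#' candidate-candidate hits with bitscore `< min_cmip_bitscore` are
#' discarded (a hit at exactly 30.0 bits is kept); target hits with
#' bitscore `< target_bit_min` or `> target_bit_max` are discarded
#' (endpoints kept); candidates with `> max_homologs` homologs are
#' excluded (exactly `max_homologs` is kept); targets less than
#' `length_margin` residues longer than the candidate are removed (a
#' difference of exactly `length_margin` is kept).
#'
#' @param size_boundary residue count separating candidate microProteins
#'   (`length <= size_boundary`) from potential targets.
#' @param min_cmip_bitscore bitscore gate for candidate-candidate homology
#'   (also reused as the cross-species conservation threshold).
#' @param target_bit_min,target_bit_max closed bitscore window for target
#'   hits; hits below the window are noise, hits above it are "too similar"
#'   to be a trimmed descendant.
#' @param top_hits number of best target hits kept per candidate.
#' @param max_homologs maximum allowed homolog count per candidate (a
#'   smaller proteome may warrant lowering this, e.g. to 8 for the reviewed
#'   Arabidopsis proteome).
#' @param max_existence maximum UniProt protein-existence level kept;
#'   proteins at level 5 ("existence uncertain") are removed, proteins with
#'   no recorded level are kept.
#' @param length_margin minimum residue-count difference between a target
#'   and its microProtein.
#' @param top_fraction proportion of ranked pairs flagged high-confidence.
#' @param drop_unannotated if `TRUE`, the domain-architecture filter also
#'   removes targets with no InterPro Domain entry (strict two-or-more
#'   domain reading); by default unannotated targets are kept so poorly
#'   annotated proteomes are not emptied.
#' @param restrict_conservation_to_small if `TRUE`, cross-species
#'   conservation searches only the other species' small proteins rather
#'   than their full proteomes.
#' @return An object of class `pipeline_params`.
#' @export
pipeline_params <- function(size_boundary = 150L,
                            min_cmip_bitscore = 30.0,
                            target_bit_min = 10,
                            target_bit_max = 120,
                            top_hits = 10L,
                            max_homologs = 10L,
                            max_existence = 4L,
                            length_margin = 40L,
                            top_fraction = 0.10,
                            drop_unannotated = FALSE,
                            restrict_conservation_to_small = FALSE) {
  stopifnot(size_boundary > 0, min_cmip_bitscore > 0, target_bit_min > 0,
            target_bit_max > target_bit_min, top_hits > 0, max_homologs > 0,
            max_existence >= 1, length_margin > 0,
            top_fraction > 0, top_fraction <= 1)
  structure(list(size_boundary = as.integer(size_boundary),
                 min_cmip_bitscore = min_cmip_bitscore,
                 target_bit_min = target_bit_min,
                 target_bit_max = target_bit_max,
                 top_hits = as.integer(top_hits),
                 max_homologs = as.integer(max_homologs),
                 max_existence = as.integer(max_existence),
                 length_margin = as.integer(length_margin),
                 top_fraction = top_fraction,
                 drop_unannotated = isTRUE(drop_unannotated),
                 restrict_conservation_to_small =
                   isTRUE(restrict_conservation_to_small)),
            class = "pipeline_params")
}

stage_log <- function(stage, kept, dropped)
  message(sprintf("stage=%s kept=%d dropped=%d", stage, kept, dropped))

#' Remove proteins whose existence is uncertain
#'
#' Drops proteins with a recorded UniProt existence level of 5 (or more
#' generally above `max_existence`); proteins with no recorded level are
#' kept, since absence of evidence for level 5 must not exclude.
#'
#' @param x an annotated [proteome].
#' @param params a [pipeline_params()] object.
#' @return The filtered proteome.
#' @export
filter_existence <- function(x, params = pipeline_params()) {
  keep <- is.na(x$existence) | x$existence <= params$max_existence
  stage_log("existence", sum(keep), sum(!keep))
  x[keep]
}

#' Partition a proteome at the size boundary
#'
#' @param x an (existence-filtered) [proteome].
#' @inheritParams filter_existence
#' @return List with elements `cmips` (proteins of length
#'   `<= size_boundary`) and `targets` (the rest), both proteomes.
#' @export
partition_proteome <- function(x, params = pipeline_params()) {
  len <- protein_lengths(x)
  small <- len <= params$size_boundary
  stage_log("partition", sum(small), sum(!small))
  list(cmips = x[small], targets = x[!small])
}

new_group <- function(seed_id, homolog_ids) {
  structure(list(seed_id = seed_id,
                 homolog_ids = sort(unique(homolog_ids)),
                 single_copy = length(homolog_ids) == 0L,
                 target_hits = empty_hits()),
            class = "candidate_group")
}

#' @export
print.candidate_group <- function(x, ...) {
  cat(sprintf("candidate group '%s': %s, %d target hit(s)\n", x$seed_id,
              if (x$single_copy) "single-copy"
              else sprintf("%d homolog(s)", length(x$homolog_ids)),
              nrow(x$target_hits)))
  invisible(x)
}

#' Cluster candidate microProteins by all-vs-all homology
#'
#' Every candidate is compared against every other; hits at or above
#' `min_cmip_bitscore` (in either search direction - homology is made
#' symmetric) link the two candidates. Candidates with no link are flagged
#' single-copy.
#'
#' @param cmips [proteome] of candidate microProteins.
#' @inheritParams filter_existence
#' @param backend a [mip_backend()] object.
#' @return Named list of `candidate_group` objects, one per candidate.
#' @export
cluster_cmips <- function(cmips, params = pipeline_params(),
                          backend = mip_backend()) {
  ids <- protein_ids(cmips)
  if (length(ids) == 0L) stop("no candidates: empty candidate set")
  hits <- pairwise_search(cmips, cmips, backend,
                          min_bitscore = params$min_cmip_bitscore)
  links <- setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(hits))) {
    q <- hits$query_id[k]; s <- hits$subject_id[k]
    links[[q]] <- c(links[[q]], s)
    links[[s]] <- c(links[[s]], q)   # either direction counts
  }
  groups <- lapply(ids, function(id) new_group(id, links[[id]]))
  names(groups) <- ids
  stage_log("cluster", sum(!vapply(groups, `[[`, logical(1), "single_copy")),
            sum(vapply(groups, `[[`, logical(1), "single_copy")))
  groups
}

#' Find target hits for one candidate group
#'
#' A single-copy candidate is searched directly against the targets; a
#' candidate with homologs is represented by the profile of its homolog
#' group (seed plus homologs) which is then searched against the targets.
#' Hits outside the closed bitscore window
#' `[target_bit_min, target_bit_max]` are discarded and the `top_hits`
#' best-scoring hits are kept (ties broken by ascending target id).
#'
#' @param group a `candidate_group` from [cluster_cmips()].
#' @param cmips the candidate proteome (supplies homolog sequences).
#' @param targets the target proteome.
#' @inheritParams cluster_cmips
#' @return The group with `target_hits` populated.
#' @export
find_targets <- function(group, cmips, targets, params = pipeline_params(),
                         backend = mip_backend()) {
  if (length(targets) == 0L) {
    group$target_hits <- empty_hits()
    return(group)
  }
  hits <- if (group$single_copy) {
    pairwise_search(cmips[group$seed_id], targets, backend)
  } else {
    # seed first so the profile is anchored on the candidate itself
    members <- as_seq_vector(cmips)[c(group$seed_id, group$homolog_ids)]
    prof <- align_group(members, backend)
    profile_search(prof, targets, backend)
  }
  hits <- hits[hits$bitscore >= params$target_bit_min &
               hits$bitscore <= params$target_bit_max, , drop = FALSE]
  hits <- hits[order(-hits$bitscore, hits$subject_id, method = "radix"), ,
               drop = FALSE]
  group$target_hits <- utils::head(hits, params$top_hits)
  rownames(group$target_hits) <- NULL
  group
}

#' Remove single-domain targets
#'
#' Drops, from every group's hit list, targets annotated with exactly one
#' distinct InterPro entry of type `Domain` (a single-domain protein cannot
#' both dimerize with the microProtein and retain another functional
#' domain). Entries of other types (Family, Repeat, Site, ...) are not
#' counted. Targets with no Domain entry are kept unless
#' `params$drop_unannotated` is set. If the proteome carries no InterPro
#' annotation at all the filter is skipped with a prominent warning.
#'
#' @param groups list of `candidate_group` objects.
#' @param x the annotated [proteome] (supplies InterPro entries).
#' @inheritParams filter_existence
#' @return The filtered group list.
#' @export
filter_target_domains <- function(groups, x, params = pipeline_params()) {
  if (all(vapply(x$interpro, is.null, logical(1)))) {
    warning("proteome has no InterPro annotations: ",
            "single-domain target filter SKIPPED", call. = FALSE)
    return(groups)
  }
  before <- sum(vapply(groups, function(g) nrow(g$target_hits), integer(1)))
  tids <- unique(unlist(lapply(groups, function(g) g$target_hits$subject_id)))
  ndom <- setNames(vapply(tids, function(id) n_domain_entries(x, id),
                          integer(1)), tids)
  groups <- lapply(groups, function(g) {
    nd <- ndom[g$target_hits$subject_id]
    drop <- nd == 1L | (params$drop_unannotated & nd == 0L)
    g$target_hits <- g$target_hits[!drop, , drop = FALSE]
    g
  })
  after <- sum(vapply(groups, function(g) nrow(g$target_hits), integer(1)))
  stage_log("domain_filter", after, before - after)
  groups
}

#' Exclude candidates from oversized homolog families
#'
#' Removes groups whose candidate has more than `max_homologs` homologous
#' candidates (exactly `max_homologs` is kept): members of large conserved
#' small-protein families (calmodulins, thioredoxins, ...) match the other
#' microProtein criteria but are unlikely regulators.
#'
#' @inheritParams filter_target_domains
#' @return The filtered group list.
#' @export
filter_homolog_count <- function(groups, params = pipeline_params()) {
  keep <- vapply(groups, function(g)
    length(g$homolog_ids) <= params$max_homologs, logical(1))
  stage_log("homolog_cap", sum(keep), sum(!keep))
  groups[keep]
}

#' Remove targets without a sufficient length margin
#'
#' Drops target hits whose target is less than `length_margin` residues
#' longer than the candidate: with so small a difference the target cannot
#' harbour a second domain and act as a regulated ancestor.
#'
#' @inheritParams filter_target_domains
#' @return The filtered group list.
#' @export
filter_length_margin <- function(groups, x, params = pipeline_params()) {
  len <- protein_lengths(x)
  before <- sum(vapply(groups, function(g) nrow(g$target_hits), integer(1)))
  groups <- lapply(groups, function(g) {
    if (nrow(g$target_hits) == 0L) return(g)
    diff <- len[g$target_hits$subject_id] - len[g$seed_id]
    g$target_hits <- g$target_hits[diff >= params$length_margin, ,
                                   drop = FALSE]
    g
  })
  after <- sum(vapply(groups, function(g) nrow(g$target_hits), integer(1)))
  stage_log("length_margin", after, before - after)
  groups
}

#' Run the full candidate filter cascade
#'
#' Applies, in order: existence filter, size partition, candidate
#' clustering, target discovery, domain-architecture filter, homolog-count
#' cap and length-margin filter, then drops groups left without target
#' hits. Per-stage counts are logged to the message stream.
#'
#' @param x an annotated [proteome].
#' @inheritParams cluster_cmips
#' @return List with elements `groups` (surviving `candidate_group`s),
#'   `cmips`, `targets` (the partitioned proteomes) and `counts` (named
#'   stage bookkeeping vector).
#' @export
run_cascade <- function(x, params = pipeline_params(),
                        backend = mip_backend()) {
  if (length(x) == 0L) stop("no candidates: empty proteome")
  kept <- filter_existence(x, params)
  if (length(kept) == 0L) stop("no candidates: all proteins at existence level > ",
                               params$max_existence)
  parts <- partition_proteome(kept, params)
  if (length(parts$cmips) == 0L)
    stop("no candidates: no protein at or below the size boundary")
  groups <- cluster_cmips(parts$cmips, params, backend)
  groups <- lapply(groups, find_targets, cmips = parts$cmips,
                   targets = parts$targets, params = params,
                   backend = backend)
  groups <- filter_target_domains(groups, kept, params)
  groups <- filter_homolog_count(groups, params)
  groups <- filter_length_margin(groups, kept, params)
  has_hits <- vapply(groups, function(g) nrow(g$target_hits) > 0L,
                     logical(1))
  stage_log("nonempty", sum(has_hits), sum(!has_hits))
  groups <- groups[has_hits]
  single <- vapply(groups, `[[`, logical(1), "single_copy")
  counts <- c(total = length(x),
              existence_kept = length(kept),
              targets = length(parts$targets),
              small_proteins = length(parts$cmips),
              microproteins = length(groups),
              single_copy = sum(single),
              homologous = sum(!single))
  list(groups = groups, cmips = parts$cmips, targets = parts$targets,
       counts = counts)
}

#' Screen a proteome for microProtein candidates
#'
#' The package's main entry point: runs the filter cascade
#' ([run_cascade()]), turns every surviving candidate-target hit into a
#' scored pair (coverage, instability index of the candidate sequence,
#' coverage weight, composite score) and ranks the pairs
#' ([rank_pairs()]).
#'
#' @param x an annotated [proteome].
#' @param params a [pipeline_params()] object.
#' @param sparams a [score_params()] object.
#' @param backend a [mip_backend()] object.
#' @return An object of class `mip_screen` with components `pairs` (the
#'   ranked pair table), `groups`, `counts`, `params`, `sparams`.
#' @examples
#' sim <- simulate_proteome(n_ancestors = 3, n_decoys_per_class = 2, seed = 1)
#' res <- mip_screen(sim$proteome)
#' head(res$pairs)
#' @export
mip_screen <- function(x, params = pipeline_params(),
                       sparams = score_params(), backend = mip_backend()) {
  cas <- run_cascade(x, params, backend)
  pairs <- pairs_from_groups(cas$groups, x, params, sparams)
  pairs <- rank_pairs(pairs, params)
  structure(list(pairs = pairs, groups = cas$groups, counts = cas$counts,
                 params = params, sparams = sparams),
            class = "mip_screen")
}

pairs_from_groups <- function(groups, x, params = pipeline_params(),
                              sparams = score_params()) {
  len <- protein_lengths(x)
  ii_cache <- new.env(parent = emptyenv())
  rows <- lapply(groups, function(g) {
    h <- g$target_hits
    if (nrow(h) == 0L) return(NULL)
    if (is.null(ii_cache[[g$seed_id]]))
      ii_cache[[g$seed_id]] <- instability_index(x$seqs[[g$seed_id]])
    ii <- ii_cache[[g$seed_id]]
    cov <- coverage(len[[g$seed_id]], len[h$subject_id])
    data.frame(mip_id = g$seed_id, target_id = h$subject_id,
               bitscore = h$bitscore,
               mip_length = len[[g$seed_id]],
               target_length = unname(len[h$subject_id]),
               coverage = unname(cov),
               instability_index = ii,
               weight = unname(coverage_weight(cov, sparams)),
               score = unname(score_pair(h$bitscore, cov, ii, sparams)),
               single_copy = g$single_copy,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(mip_id = character(0), target_id = character(0),
                      bitscore = numeric(0), mip_length = integer(0),
                      target_length = integer(0), coverage = numeric(0),
                      instability_index = numeric(0), weight = numeric(0),
                      score = numeric(0), single_copy = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mip_screen <- function(x, ...) {
  cat("microProtein screen\n")
  print(summary(x))
  invisible(x)
}

#' @method summary mip_screen
#' @export
summary.mip_screen <- function(object, ...) {
  co <- object$counts
  n <- nrow(object$pairs)
  out <- c(co,
           pairs = n,
           high_confidence_pairs = sum(object$pairs$high_confidence))
  class(out) <- c("summary.mip_screen", class(out))
  out
}

#' @export
print.summary.mip_screen <- function(x, ...) {
  lab <- c(total = "Total proteins", existence_kept = "After existence filter",
           targets = "Targets", small_proteins = "Small proteins",
           microproteins = "MicroProteins", single_copy = "Single-copy",
           homologous = "Homologous", pairs = "Scored pairs",
           high_confidence_pairs = "High-confidence pairs")
  for (k in names(lab))
    if (k %in% names(x)) cat(sprintf("  %-24s %d\n", lab[[k]], x[[k]]))
  invisible(x)
}

#' @method plot mip_screen
#' @export
plot.mip_screen <- function(x, breaks = 30, ...) {
  graphics::hist(x$pairs$score, breaks = breaks,
                 main = "Score distribution of candidate microProteins",
                 xlab = "composite score", ...)
  invisible(x)
}

#' Histogram of pair scores as a table
#'
#' Bins the composite scores of a ranked screen into a (score_bin, count)
#' table, the tabular analogue of the score-distribution figure.
#'
#' @param screen a `mip_screen` object.
#' @param n_bins number of equal-width bins over the score range.
#' @return data.frame with `bin_lower`, `bin_upper`, `count`.
#' @export
score_histogram <- function(screen, n_bins = 30L) {
  s <- screen$pairs$score
  if (!length(s))
    return(data.frame(bin_lower = numeric(0), bin_upper = numeric(0),
                      count = integer(0)))
  br <- seq(0, max(s) * (1 + 1e-9), length.out = n_bins + 1L)
  ct <- table(cut(s, br, include.lowest = TRUE))
  data.frame(bin_lower = br[-length(br)], bin_upper = br[-1L],
             count = as.integer(ct))
}
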