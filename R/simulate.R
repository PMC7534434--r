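# Synthetic proteomes with planted ground truth.
#
# The generator emulates the trans-microProtein birth process: a multidomain
# ancestor is duplicated and the copy trimmed down to one domain, after
# which the sequence outside the retained interaction core drifts. A
# planted candidate therefore consists of a conserved core (a slice of one
# ancestor domain copied with point mutations) flanked by freshly drawn
# padding. The padding is bias-sampled so the candidate's instability index
# lands above the scoring sigmoid's midpoint, as observed for real
# microProteins, while decoy small proteins are drawn from a stabilising
# residue pool. Keeping the conserved core short (35-45 residues) keeps
# the candidate-ancestor bitscore inside the pipeline's target window:
# a full-length near-identical duplicate would exceed the upper "too
# similar" gate and be discarded by design.

# residue pools (see vignette): the unstable pool enriches dipeptides with
# high instability weights, the stable pool the opposite; both keep the
# expected BLOSUM50 score of unrelated sequence pairs negative so
# composition bias alone does not create homology.
.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.pool_unstable <- c("S", "P", "R", "E", "Q", "M", "H", "I", "Y")
.pool_stable <- c("G", "T", "V", "N", "K", "D", "A", "F")

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_residues <- function(n, pool = .aa20) {
  sample(pool, n, replace = TRUE)
}

# biased mixtures: enough pool bias to shift the instability index, little
# enough that unrelated padding/decoy sequences stay non-homologous
unstable_residues <- function(n) {
  ifelse(runif(n) < 0.45, sample(.pool_unstable, n, replace = TRUE),
         sample(.aa20, n, replace = TRUE))
}

stable_residues <- function(n) {
  ifelse(runif(n) < 0.6, sample(.pool_stable, n, replace = TRUE),
         sample(.aa20, n, replace = TRUE))
}

mutate_residues <- function(res, rate) {
  hit <- which(runif(length(res)) < rate)
  for (i in hit) res[i] <- sample(setdiff(.aa20, res[i]), 1L)
  res
}

seq_ii <- function(res) instability_index(paste(res, collapse = ""))

# raise the instability index to at least min_ii by single-residue swaps in
# editable (padding) positions, each chosen from a random candidate set for
# its local dipeptide-weight gain; randomising the candidates keeps the
# inserted residues diverse across candidates so the top-up itself does not
# create homology between unrelated paddings
raise_instability <- function(res, editable, min_ii = 75, max_iter = 300L) {
  inner <- editable[editable > 1L & editable < length(res)]
  it <- 0L
  while (seq_ii(res) < min_ii && it < max_iter && length(inner)) {
    i <- if (length(inner) == 1L) inner else sample(inner, 1L)
    cand <- sample(.diwv_aas, 8L)
    gain <- .DIWV[cbind(res[i - 1L], cand)] + .DIWV[cbind(cand, res[i + 1L])]
    res[i] <- cand[which.max(gain)]
    it <- it + 1L
  }
  res
}

# lower the instability index to at most max_ii by swapping in stabilising
# residues
lower_instability <- function(res, max_ii = 35, max_iter = 200L) {
  it <- 0L
  while (seq_ii(res) > max_ii && it < max_iter) {
    i <- sample(length(res) - 1L, 1L)
    res[i] <- sample(c("G", "T", "V", "A"), 1L)
    res[i + 1L] <- sample(c("G", "T", "V", "A"), 1L)
    it <- it + 1L
  }
  res
}

.go_vocab <- paste0("GO:", sprintf("%07d",
  c(6355, 9414, 9737, 9640, 48366, 10075, 80167, 9733)))

#' Simulate a proteome with planted microProteins and decoys
#'
#' Generates a synthetic proteome containing multidomain ancestors,
#' planted trans-microProteins derived from them, and decoy classes that
#' each trip exactly one cascade filter, together with matching
#' annotations and a ground-truth table:
#'
#' * ancestors (`ANC...`): 250-600 residues with 2-4 annotated
#'   InterPro Domain entries; potential targets.
#' * planted microProteins (`MIP...`): one per ancestor (a second copy for
#'   every third ancestor, exercising the homolog-profile search path).
#'   Each is a 60-140 residue protein holding a 35-45 residue core copied
#'   from one ancestor domain with point mutations at `mutation_rate`,
#'   flanked by fresh high-instability padding (whole-sequence instability
#'   index >= 70), annotated with that single Domain entry and an
#'   existence level of 1-4.
#' * `small_unrelated` decoys (`DSU...`): random 60-100 residue proteins
#'   from a stabilising residue pool (instability index well below 40);
#'   weakly hit targets and form the low-scoring background of the
#'   ranking.
#' * `large_single_domain` decoys (`DLD...`): >150-residue proteins with
#'   exactly one Domain entry; removed wherever they appear as targets.
#' * `existence5` decoys (`DE5...`): small proteins at existence level 5;
#'   removed by the existence filter.
#' * `big_family_member` decoys (`FAM...`): one family of `family_size`
#'   (>= 11) near-identical small proteins; each member has more homologs
#'   than the cap allows and is excluded.
#'
#' All randomness flows from `seed`; the caller's RNG state is restored on
#' exit, and a fixed seed gives byte-identical output.
#'
#' @param n_ancestors number of multidomain ancestors (>= 1).
#' @param n_decoys_per_class decoys per class: either a single count
#'   applied to the `small_unrelated`, `large_single_domain` and
#'   `existence5` classes, or a named vector/list overriding any of them.
#'   The default generates 250 small unrelated proteins - the dominant
#'   class in real proteomes and the background the top-fraction selection
#'   needs - and 6 of each pathological class.
#' @param seed integer seed driving all randomness.
#' @param mutation_rate per-residue substitution probability applied to the
#'   conserved core copied from the ancestor.
#' @param family_size members of the homolog-cap decoy family (0 disables;
#'   values 1-10 would not trip the cap and are rejected).
#' @return List with components `proteome` (annotated [proteome]),
#'   `annotations` (data.frame mirroring the annotation TSV) and `truth`
#'   (list with data.frames `planted` and `decoys`).
#' @export
simulate_proteome <- function(n_ancestors = 20L,
                              n_decoys_per_class = c(small_unrelated = 250L,
                                                     large_single_domain = 6L,
                                                     existence5 = 6L),
                              seed = 1L,
                              mutation_rate = 0.05,
                              family_size = 12L) {
  stopifnot(n_ancestors >= 1, mutation_rate >= 0, mutation_rate < 1)
  if (family_size != 0L && family_size < 11L)
    stop("family_size must be 0 or at least 11 to trip the homolog cap")
  classes <- c("small_unrelated", "large_single_domain", "existence5")
  if (is.null(names(n_decoys_per_class))) {
    stopifnot(length(n_decoys_per_class) == 1L)
    nd <- setNames(rep(as.integer(n_decoys_per_class), 3L), classes)
  } else {
    nd <- setNames(rep(0L, 3L), classes)
    nd[names(n_decoys_per_class)] <- as.integer(unlist(n_decoys_per_class))
  }
  with_seed(seed, {
    seqs <- character(0); existence <- integer(0)
    interpro <- list(); go <- list()
    planted <- list(); decoys <- list()
    ipr_counter <- 0L

    for (a in seq_len(n_ancestors)) {
      aid <- sprintf("ANC%03d", a)
      alen <- sample(250:600, 1L)
      n_dom <- sample(2:4, 1L)
      # tile domains of 60-110 residues with 10-30 residue linkers
      doms <- list()
      pos <- sample(5:20, 1L)
      for (d in seq_len(n_dom)) {
        dlen <- sample(60:110, 1L)
        if (pos + dlen > alen - 5L) break
        ipr_counter <- ipr_counter + 1L
        doms[[length(doms) + 1L]] <- list(
          id = sprintf("IPR%05d", ipr_counter),
          start = pos, end = pos + dlen - 1L)
        pos <- pos + dlen + sample(10:30, 1L)
      }
      if (length(doms) < 2L) {  # very short ancestor: force two domains
        ipr_counter <- ipr_counter + 1L
        doms[[2L]] <- list(id = sprintf("IPR%05d", ipr_counter),
                           start = alen - 70L, end = alen - 11L)
      }
      ares <- random_residues(alen)
      seqs[[aid]] <- paste(ares, collapse = "")
      existence[[aid]] <- sample(1:4, 1L)
      interpro[[aid]] <- data.frame(
        entry_id = vapply(doms, `[[`, character(1), "id"),
        entry_type = "Domain", stringsAsFactors = FALSE)
      go[[aid]] <- sample(.go_vocab, sample(1:3, 1L))

      src <- doms[[sample(length(doms), 1L)]]
      n_copies <- if (a %% 3L == 0L) 2L else 1L
      # short conserved core: long enough to clear the 30-bit homology
      # gate against the ancestor, short enough to stay below the
      # 120-bit "too similar" gate
      core_len <- sample(28:38, 1L)
      core_start <- src$start +
        sample(0:max(0L, (src$end - src$start + 1L) - core_len), 1L)
      core <- ares[core_start:(core_start + core_len - 1L)]
      for (cp in seq_len(n_copies)) {
        mid <- sprintf("MIP%03d%s", a, letters[cp])
        mlen <- max(core_len + 20L,
                    min(140L, round(alen * runif(1L, 0.25, 0.45))))
        mlen <- max(60L, mlen)
        pad_total <- mlen - core_len
        pad_left <- sample(5:(pad_total - 5L), 1L)
        mres <- c(unstable_residues(pad_left),
                  mutate_residues(core, mutation_rate),
                  unstable_residues(pad_total - pad_left))
        editable <- c(seq_len(pad_left),
                      (pad_left + core_len + 1L):mlen)
        mres <- raise_instability(mres, editable)
        seqs[[mid]] <- paste(mres, collapse = "")
        existence[[mid]] <- sample(1:4, 1L)
        interpro[[mid]] <- data.frame(entry_id = src$id,
                                      entry_type = "Domain",
                                      stringsAsFactors = FALSE)
        go[[mid]] <- sample(go[[aid]], 1L)
        planted[[length(planted) + 1L]] <- data.frame(
          mip_id = mid, ancestor_id = aid,
          span_start = core_start, span_end = core_start + core_len - 1L,
          expected_coverage = mlen / alen, stringsAsFactors = FALSE)
      }
    }

    for (k in seq_len(nd[["small_unrelated"]])) {
      id <- sprintf("DSU%03d", k)
      res <- lower_instability(stable_residues(sample(60:120, 1L)))
      seqs[[id]] <- paste(res, collapse = "")
      existence[[id]] <- sample(1:4, 1L)
      decoys[[length(decoys) + 1L]] <- data.frame(
        id = id, decoy_class = "small_unrelated", stringsAsFactors = FALSE)
    }
    for (k in seq_len(nd[["large_single_domain"]])) {
      id <- sprintf("DLD%03d", k)
      seqs[[id]] <- paste(random_residues(sample(250:600, 1L)),
                          collapse = "")
      existence[[id]] <- sample(1:4, 1L)
      ipr_counter <- ipr_counter + 1L
      interpro[[id]] <- data.frame(entry_id = sprintf("IPR%05d", ipr_counter),
                                   entry_type = "Domain",
                                   stringsAsFactors = FALSE)
      decoys[[length(decoys) + 1L]] <- data.frame(
        id = id, decoy_class = "large_single_domain",
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(nd[["existence5"]])) {
      id <- sprintf("DE5%03d", k)
      seqs[[id]] <- paste(random_residues(sample(60:140, 1L)), collapse = "")
      existence[[id]] <- 5L
      decoys[[length(decoys) + 1L]] <- data.frame(
        id = id, decoy_class = "existence5", stringsAsFactors = FALSE)
    }
    if (family_size >= 11L) {
      template <- random_residues(sample(90:120, 1L), .pool_stable)
      for (k in seq_len(family_size)) {
        id <- sprintf("FAM%03d", k)
        seqs[[id]] <- paste(mutate_residues(template, 0.03), collapse = "")
        existence[[id]] <- sample(1:4, 1L)
        decoys[[length(decoys) + 1L]] <- data.frame(
          id = id, decoy_class = "big_family_member",
          stringsAsFactors = FALSE)
      }
    }

    prot <- proteome(seqs, existence = existence, interpro = interpro,
                     go = go, source_label = sprintf("synthetic seed %d", seed))
    truth <- list(planted = do.call(rbind, planted),
                  decoys = do.call(rbind, decoys))
    ann <- annotation_frame(prot)
    list(proteome = prot, annotations = ann, truth = truth)
  })
}

annotation_frame <- function(x) {
  ids <- protein_ids(x)
  data.frame(
    protein_id = ids,
    existence_level = unname(x$existence[ids]),
    interpro = vapply(ids, function(id) {
      d <- x$interpro[[id]]
      if (is.null(d) || nrow(d) == 0L) "" else
        paste(paste0(d$entry_id, ":", d$entry_type), collapse = ";")
    }, character(1)),
    go = vapply(ids, function(id) paste(x$go[[id]], collapse = ";"),
                character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate ortholog proteomes for conservation testing
#'
#' Builds `n_species` companion proteomes: each planted microProtein of
#' `sim` is conserved in a per-candidate number of species (drawn from
#' `conservation_profile`); a conserved copy is the full candidate sequence
#' with point mutations at `mutation_rate`, embedded among unrelated filler
#' proteins.
#'
#' @param sim result of [simulate_proteome()].
#' @param n_species number of companion proteomes.
#' @param seed integer seed.
#' @param mutation_rate per-residue substitution probability of conserved
#'   copies.
#' @param conservation_profile probabilities that a candidate family is
#'   conserved in 0, 1, ..., `n_species` species. Conservation is drawn per
#'   ancestor family, not per candidate: sibling candidates share their
#'   interaction core, so a homology search cannot tell them apart and a
#'   per-candidate truth would be unverifiable. The default plants clearly
#'   conserved (3-4 species) and clearly non-conserved (0-1 species)
#'   families; exactly-at-boundary counting is a property of the counting
#'   rule, not of sequence content, and is better exercised with injected
#'   bitscores.
#' @param n_filler unrelated filler proteins per companion proteome.
#' @return List with `proteomes` (named list of [proteome]s) and `truth`
#'   (data.frame `mip_id`, `n_species`).
#' @export
simulate_orthologs <- function(sim, n_species = 4L, seed = 1L,
                               mutation_rate = 0.05,
                               conservation_profile = c(0.25, 0.15, 0,
                                                        0.3, 0.3),
                               n_filler = 20L) {
  stopifnot(length(conservation_profile) == n_species + 1L)
  planted <- sim$truth$planted
  mips <- unique(planted$mip_id)
  anc_of <- setNames(planted$ancestor_id, planted$mip_id)[mips]
  families <- unique(anc_of)
  # offset the substream so companion proteomes never replay the residue
  # draws of the focal proteome
  with_seed((seed + 1000003L) %% .Machine$integer.max, {
    fam_in <- sample(0:n_species, length(families), replace = TRUE,
                     prob = conservation_profile)
    names(fam_in) <- families
    n_in <- fam_in[anc_of]
    names(n_in) <- mips
    proteomes <- list()
    for (sp in seq_len(n_species)) {
      label <- sprintf("species%d", sp)
      seqs <- character(0)
      for (k in seq_len(n_filler)) {
        id <- sprintf("%s_FIL%03d", label, k)
        seqs[[id]] <- paste(random_residues(sample(80:250, 1L)),
                            collapse = "")
      }
      for (m in mips) {
        if (n_in[[m]] < sp) next   # conserved in species 1..n_in
        res <- mutate_residues(strsplit(sim$proteome$seqs[[m]], "")[[1L]],
                               mutation_rate)
        seqs[[sprintf("%s_%s", label, m)]] <- paste(res, collapse = "")
      }
      proteomes[[label]] <- proteome(seqs, source_label = label)
    }
    list(proteomes = proteomes,
         truth = data.frame(mip_id = mips, n_species = unname(n_in),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a tissue expression matrix with planted pair correlations
#'
#' For each (microProtein, target) pair a bivariate normal profile with the
#' requested population correlation is drawn across `n_samples` tissues,
#' then affinely shifted and scaled to the non-negative range typical of
#' expression estimates (affine maps leave the sample correlation
#' unchanged). Genes not in any pair are independent.
#'
#' @param pairs data.frame with `mip_id` and `target_id` columns.
#' @param target_r population correlation per pair (recycled); `|r| < 1`.
#' @param n_samples number of tissue samples (columns).
#' @param seed integer seed.
#' @param extra_genes number of additional independent genes to include.
#' @return Numeric genes-by-samples matrix.
#' @export
simulate_expression <- function(pairs, target_r = 0.95, n_samples = 10L,
                                seed = 1L, extra_genes = 0L) {
  stopifnot(all(abs(target_r) < 1), n_samples >= 3)
  target_r <- rep_len(target_r, nrow(pairs))
  with_seed((seed + 2000003L) %% .Machine$integer.max, {
    rows <- list()
    for (k in seq_len(nrow(pairs))) {
      m <- pairs$mip_id[k]; t <- pairs$target_id[k]
      if (is.null(rows[[m]])) rows[[m]] <- rnorm(n_samples)
      z <- target_r[k] * rows[[m]] +
        sqrt(1 - target_r[k]^2) * rnorm(n_samples)
      rows[[t]] <- z
    }
    for (k in seq_len(extra_genes))
      rows[[sprintf("GEN%05d", k)]] <- rnorm(n_samples)
    mat <- do.call(rbind, rows)
    mat <- 100 + 15 * mat            # non-negative scale, r unchanged
    mat[mat < 0] <- 0
    colnames(mat) <- sprintf("tissue%02d", seq_len(n_samples))
    mat
  })
}

#' Write a simulated fixture to disk
#'
#' Emits the exact dialects the pipeline consumes: `proteome.fasta`,
#' `annotations.tsv` and the ground-truth tables `truth_planted.tsv` /
#' `truth_decoys.tsv`.
#'
#' @param sim result of [simulate_proteome()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "proteome.fasta"),
             file.path(dir, "annotations.tsv"),
             file.path(dir, "truth_planted.tsv"),
             file.path(dir, "truth_decoys.tsv"))
  write_proteome(sim$proteome, paths[1L])
  write_annotations(sim$proteome, paths[2L])
  write.table(sim$truth$planted, paths[3L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$decoys, paths[4L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
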