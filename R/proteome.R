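#' Construct a proteome object
#'
#' A `proteome` holds one record per protein: its amino-acid sequence plus
#' the annotations the screening cascade consumes (UniProt-style protein
#' existence level, InterPro entries with their entry types, GO terms).
#' Records are kept sorted by identifier so that iteration order, and hence
#' every downstream result table, is deterministic.
#'
#' @param seqs named character vector of amino-acid sequences; names are the
#'   protein identifiers and must be unique. The 20 canonical residues plus
#'   X, B, Z and U are accepted.
#' @param existence optional named integer vector of existence levels
#'   (1-5); proteins without a level are treated as level unknown and are
#'   kept by the existence filter.
#' @param interpro optional named list; each element a data.frame with
#'   columns `entry_id` and `entry_type` (InterPro vocabulary: "Domain",
#'   "Family", "Repeat", "Site", ...).
#' @param go optional named list of character vectors of GO identifiers.
#' @param source_label free-text label describing the proteome's origin.
#' @return An object of class `proteome`.
#' @seealso [read_proteome()], [read_annotations()]
#' @export
proteome <- function(seqs, existence = NULL, interpro = NULL, go = NULL,
                     source_label = "") {
  seqs <- vapply(seqs, as.character, character(1))
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named with protein identifiers")
  if (anyDuplicated(ids))
    stop("duplicate protein identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXBZU]", toupper(seqs))
  if (any(bad))
    stop("non amino-acid characters in sequence(s): ",
         paste(head(ids[bad], 5L), collapse = ", "))
  ord <- order(ids, method = "radix")
  seqs <- toupper(seqs)[ord]
  ids <- ids[ord]
  ex <- setNames(rep(NA_integer_, length(ids)), ids)
  if (!is.null(existence)) {
    existence <- existence[!is.na(existence)]
    if (length(existence) && !all(existence %in% 1:5))
      stop("existence levels must be integers in 1..5")
    keep <- intersect(names(existence), ids)
    ex[keep] <- as.integer(existence[keep])
  }
  ip <- setNames(vector("list", length(ids)), ids)
  if (!is.null(interpro))
    for (id in intersect(names(interpro), ids)) ip[[id]] <- interpro[[id]]
  gt <- setNames(vector("list", length(ids)), ids)
  if (!is.null(go))
    for (id in intersect(names(go), ids)) gt[[id]] <- go[[id]]
  structure(list(seqs = seqs, existence = ex, interpro = ip, go = gt,
                 source_label = source_label),
            class = "proteome")
}

#' @export
length.proteome <- function(x) length(x$seqs)

#' @export
print.proteome <- function(x, ...) {
  cat("proteome", if (nzchar(x$source_label)) sprintf("'%s'", x$source_label),
      "with", length(x), "proteins\n")
  if (length(x)) {
    len <- nchar(x$seqs)
    cat(sprintf("  length range %d-%d aa; %d with existence level, %d with InterPro entries\n",
                min(len), max(len), sum(!is.na(x$existence)),
                sum(!vapply(x$interpro, is.null, logical(1)))))
  }
  invisible(x)
}

#' @export
`[.proteome` <- function(x, i) {
  ids <- if (is.character(i)) {
    missing <- setdiff(i, protein_ids(x))
    if (length(missing))
      stop("unknown protein id(s): ", paste(head(missing, 5L), collapse = ", "))
    i
  } else protein_ids(x)[i]
  proteome(x$seqs[ids], x$existence[ids], x$interpro[ids], x$go[ids],
           x$source_label)
}

#' Protein identifiers and lengths
#'
#' @param x a [proteome] object.
#' @return `protein_ids()` the sorted identifiers; `protein_lengths()` a
#'   named integer vector of residue counts.
#' @export
protein_ids <- function(x) names(x$seqs)

#' @rdname protein_ids
#' @export
protein_lengths <- function(x) setNames(nchar(x$seqs), names(x$seqs))

#' Read a proteome from a FASTA file
#'
#' One record per FASTA entry. The identifier is the header token before the
#' first whitespace; UniProt-style headers (`db|ACC|NAME desc`) yield the
#' accession `ACC`. Annotation fields are left unset and can be attached
#' with [read_annotations()].
#'
#' @param fasta_path path to an (uncompressed or gzipped) amino-acid FASTA
#'   file.
#' @param source_label optional label; defaults to the file name.
#' @return A [proteome] object.
#' @export
read_proteome <- function(fasta_path, source_label = basename(fasta_path)) {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  set <- tryCatch(Biostrings::readAAStringSet(fasta_path),
                  error = function(e)
                    stop("malformed FASTA in ", fasta_path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    return(proteome(character(0), source_label = source_label))
  ids <- fasta_header_id(names(set))
  if (anyDuplicated(ids))
    stop("duplicate identifier(s) in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  proteome(setNames(as.character(set), ids), source_label = source_label)
}

# "sp|Q9M157|XXX desc" -> "Q9M157"; otherwise first whitespace token
fasta_header_id <- function(headers) {
  tok <- sub("\\s.*$", "", headers)
  uni <- grepl("^[a-z]{2}\\|[^|]+\\|", tok)
  tok[uni] <- vapply(strsplit(tok[uni], "|", fixed = TRUE), `[`, character(1), 2L)
  tok
}

#' Write a proteome to a FASTA file
#'
#' @param x a [proteome] object.
#' @param fasta_path output path.
#' @param width line width for the sequence block.
#' @return Invisibly, `fasta_path`.
#' @export
write_proteome <- function(x, fasta_path, width = 60L) {
  set <- Biostrings::AAStringSet(x$seqs)
  Biostrings::writeXStringSet(set, fasta_path, width = width)
  invisible(fasta_path)
}

#' Attach existence levels, InterPro entries and GO terms from a TSV table
#'
#' The annotation dialect is one row per protein with four tab-separated
#' columns: protein id, existence level (1-5, may be empty), semicolon-joined
#' `entry_id:entry_type` InterPro pairs (may be empty), and semicolon-joined
#' GO identifiers (may be empty). UniProt's tab download maps onto this
#' format with a one-line awk/dplyr reshape; see the package vignette.
#'
#' Rows for proteins absent from `x` are skipped with a warning. Proteins
#' without a row keep an unknown existence level and empty annotation sets.
#'
#' @param tsv_path path to the annotation TSV (a header line starting with
#'   `protein_id` is allowed and skipped).
#' @param x the [proteome] the annotations belong to.
#' @return The proteome with annotation fields populated.
#' @export
read_annotations <- function(tsv_path, x) {
  if (!file.exists(tsv_path)) stop("no such file: ", tsv_path)
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1L], "protein_id"))
    lines <- lines[-1L]
  ids <- protein_ids(x)
  seen <- character(0)
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    length(f) <- 4L
    id <- f[1L]
    if (is.na(id) || !nzchar(id)) next
    if (id %in% seen)
      stop("protein '", id, "' annotated more than once (row ", k, ")")
    seen <- c(seen, id)
    if (!id %in% ids) {
      warning("annotation row for unknown protein '", id, "' skipped",
              call. = FALSE)
      next
    }
    if (!is.na(f[2L]) && nzchar(f[2L])) {
      lev <- suppressWarnings(as.integer(f[2L]))
      if (is.na(lev) || !lev %in% 1:5)
        stop("row ", k, ": invalid existence level '", f[2L], "'")
      x$existence[[id]] <- lev
    }
    if (!is.na(f[3L]) && nzchar(f[3L])) {
      toks <- strsplit(f[3L], ";", fixed = TRUE)[[1L]]
      parts <- strsplit(toks, ":", fixed = TRUE)
      ok <- lengths(parts) == 2L
      if (!all(ok))
        stop("row ", k, ": malformed InterPro token '", toks[!ok][1L], "'")
      x$interpro[[id]] <- data.frame(
        entry_id = vapply(parts, `[`, character(1), 1L),
        entry_type = vapply(parts, `[`, character(1), 2L),
        stringsAsFactors = FALSE)
    }
    if (!is.na(f[4L]) && nzchar(f[4L]))
      x$go[[id]] <- strsplit(f[4L], ";", fixed = TRUE)[[1L]]
  }
  x
}

#' Write an annotation TSV in the dialect read by [read_annotations()]
#'
#' @param x an annotated [proteome].
#' @param tsv_path output path.
#' @return Invisibly, `tsv_path`.
#' @export
write_annotations <- function(x, tsv_path) {
  ids <- protein_ids(x)
  ip <- vapply(ids, function(id) {
    d <- x$interpro[[id]]
    if (is.null(d) || nrow(d) == 0L) "" else
      paste(paste0(d$entry_id, ":", d$entry_type), collapse = ";")
  }, character(1))
  go <- vapply(ids, function(id)
    paste(x$go[[id]], collapse = ";"), character(1))
  ex <- ifelse(is.na(x$existence[ids]), "", x$existence[ids])
  lines <- c("protein_id\texistence_level\tinterpro\tgo",
             paste(ids, ex, ip, go, sep = "\t"))
  writeLines(lines, tsv_path)
  invisible(tsv_path)
}

#' Read GO term names from an OBO core ontology file
#'
#' Minimal parser extracting `id` and `name` from `[Term]` stanzas; used
#' only to attach readable names to GO identifiers in reports.
#'
#' @param obo_path path to an OBO file.
#' @return Named character vector mapping GO ids to term names.
#' @export
read_go_obo <- function(obo_path) {
  if (!file.exists(obo_path)) stop("no such file: ", obo_path)
  lines <- readLines(obo_path)
  ids <- character(0); nms <- character(0)
  in_term <- FALSE; cur_id <- NA_character_
  for (ln in lines) {
    if (ln == "[Term]") { in_term <- TRUE; cur_id <- NA_character_; next }
    if (startsWith(ln, "[")) { in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id: ")) cur_id <- sub("^id: ", "", ln)
    if (startsWith(ln, "name: ") && !is.na(cur_id)) {
      ids <- c(ids, cur_id); nms <- c(nms, sub("^name: ", "", ln))
      cur_id <- NA_character_
    }
  }
  setNames(nms, ids)
}

# count of distinct InterPro entries of type "Domain" for one protein
n_domain_entries <- function(x, id) {
  d <- x$interpro[[id]]
  if (is.null(d) || nrow(d) == 0L) return(0L)
  length(unique(d$entry_id[d$entry_type == "Domain"]))
}
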