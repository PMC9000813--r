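#' Sequence sets as tibbles
#'
#' A *sequence set* is an ordinary tibble with one row per sequence record and
#' columns:
#' \describe{
#'   \item{id}{character, unique within the set (FASTA header token before the
#'     first whitespace).}
#'   \item{taxon}{character, free text (rest of the FASTA header; may be
#'     empty).}
#'   \item{group}{character, one of `"ingroup"`, `"outgroup"`, `"query"`;
#'     homogeneous within a set.}
#'   \item{residues}{character, uppercase IUPAC nucleotides with `U`
#'     normalized to `T` and gap characters stripped.}
#' }
#' All package functions accept and return these tibbles, so pipelines
#' compose with the usual dplyr verbs.
#'
#' @param id Character vector of unique record identifiers.
#' @param residues Character vector of nucleotide strings (normalized on
#'   construction).
#' @param group Group tag for every record: `"ingroup"`, `"outgroup"` or
#'   `"query"`.
#' @param taxon Optional character vector of taxon labels (recycled if length
#'   one).
#' @return A tibble with columns `id`, `taxon`, `group`, `residues`.
#' @examples
#' sequence_set(c("s1", "s2"), c("ACGT", "acgu-"), group = "ingroup")
#' @export
sequence_set <- function(id, residues, group = c("ingroup", "outgroup", "query"),
                         taxon = "") {
  group <- match.arg(group)
  id <- as.character(id)
  taxon <- rep_len(as.character(taxon), length(id))
  residues <- normalize_residues(as.character(residues), id = id)
  out <- tibble::tibble(id = id, taxon = taxon, group = group, residues = residues)
  validate_sequence_set(out)
}

#' Validate a sequence-set tibble
#'
#' Checks the sequence-set contract: required columns present, ids unique,
#' a single group tag, residues non-empty and IUPAC-only.
#'
#' @param seqs A sequence-set tibble (see [sequence_set()]).
#' @return `seqs`, invisibly unchanged, for piping.
#' @export
validate_sequence_set <- function(seqs) {
  stopifnot(is.data.frame(seqs))
  needed <- c("id", "residues")
  missing_cols <- setdiff(needed, names(seqs))
  if (length(missing_cols) > 0L) {
    stop("sequence set is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- seqs$id[duplicated(seqs$id)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if ("group" %in% names(seqs) && nrow(seqs) > 0L) {
    grp <- unique(seqs$group)
    if (length(grp) > 1L) {
      stop("sequence set mixes group tags: ", paste(grp, collapse = ", "), call. = FALSE)
    }
    if (!grp %in% c("ingroup", "outgroup", "query")) {
      stop("unknown group tag '", grp, "'", call. = FALSE)
    }
  }
  if (nrow(seqs) > 0L) {
    if (any(!nzchar(seqs$residues))) {
      stop("empty residues for record(s): ",
           paste(seqs$id[!nzchar(seqs$residues)], collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(seqs))) encode_residues(seqs$residues[[i]])
  }
  invisible(seqs)
}

#' Read a FASTA file into a sequence-set tibble
#'
#' Residues are normalized on ingest: uppercased, RNA `U` converted to `T`,
#' alignment gaps (`-`, `.`) stripped. The header token before the first
#' whitespace becomes `id`; the remainder becomes `taxon`. Files ending in
#' `.gz` are decompressed transparently.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @param group Group tag to assign: `"ingroup"`, `"outgroup"` or `"query"`.
#' @return A sequence-set tibble (see [sequence_set()]).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, group = c("ingroup", "outgroup", "query")) {
  group <- match.arg(group)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble::tibble(id = character(), taxon = character(),
                          group = character(), residues = character()))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  taxon <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers),
                  "")
  sequence_set(id = id, residues = as.character(set), group = group, taxon = taxon)
}

#' Write a sequence-set tibble to FASTA
#'
#' Standard FASTA with 60-column line wrapping and headers of the form
#' `id taxon` (just `id` when the taxon is empty). A `.gz` extension writes
#' gzip-compressed output.
#'
#' @param seqs A sequence-set tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fasta()]
#' @export
write_fasta <- function(seqs, path) {
  validate_sequence_set(seqs)
  if (nrow(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(seqs$residues)
  taxon <- if ("taxon" %in% names(seqs)) seqs$taxon else ""
  names(set) <- ifelse(nzchar(taxon), paste(seqs$id, taxon), seqs$id)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
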