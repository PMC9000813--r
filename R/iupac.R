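#' IUPAC nucleotide alphabet helpers
#'
#' The package works on the 15-letter IUPAC nucleotide alphabet
#' (`A C G T R Y S W K M B D H V N`). Each symbol denotes a set of the four
#' bases; two symbols are *compatible* when their base sets intersect.
#'
#' @name iupac
#' @keywords internal
NULL

# bitmask encoding: A=1, C=2, G=4, T=8; ambiguity codes are unions
.iupac_bits <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

.iupac_chars <- names(.iupac_bits)

# complement map (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S, W, N fixed)
.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

# byte-indexed lookup tables for fast encoding
.iupac_lut <- local({
  lut <- rep(NA_integer_, 256L)
  for (ch in .iupac_chars) lut[utf8ToInt(ch)] <- .iupac_bits[[ch]]
  lut
})

#' Encode residues as IUPAC bitmask integers
#'
#' @param residues A single residue string (already normalized, uppercase).
#' @return Integer vector of base-set bitmasks, one per residue.
#' @keywords internal
#' @noRd
encode_residues <- function(residues) {
  codes <- .iupac_lut[utf8ToInt(residues)]
  if (anyNA(codes)) {
    bad <- substr(residues, which(is.na(codes))[1L], which(is.na(codes))[1L])
    stop("invalid IUPAC nucleotide symbol '", bad, "'", call. = FALSE)
  }
  codes
}

#' Normalize a nucleotide string
#'
#' Uppercases, converts RNA `U` to `T`, strips alignment gap characters
#' (`-` and `.`), and validates that every remaining symbol is one of the 15
#' IUPAC nucleotide codes. Normalization is idempotent.
#'
#' @param residues Character vector of nucleotide strings.
#' @param id Optional record identifier(s) used in error messages.
#' @return Character vector of normalized residue strings.
#' @examples
#' normalize_residues("acgu-")
#' @export
normalize_residues <- function(residues, id = NULL) {
  out <- toupper(residues)
  out <- gsub("[-.]", "", out)
  out <- gsub("U", "T", out, fixed = TRUE)
  for (i in seq_along(out)) {
    codes <- .iupac_lut[utf8ToInt(out[[i]])]
    if (anyNA(codes)) {
      pos <- which(is.na(codes))[1L]
      bad <- substr(out[[i]], pos, pos)
      where <- if (!is.null(id)) paste0(" in record '", id[[min(i, length(id))]], "'") else ""
      stop("non-IUPAC nucleotide symbol '", bad, "'", where, call. = FALSE)
    }
  }
  out
}

#' Reverse complement of IUPAC nucleotide strings
#'
#' Standard IUPAC complementation (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H;
#' S, W and N are self-complementary) followed by reversal. An involution:
#' `reverse_complement(reverse_complement(x))` equals `x`.
#'
#' @param residues Character vector of IUPAC nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("ATGCGAAGGTCCCCTTTT")
#' @export
reverse_complement <- function(residues) {
  if (length(residues) == 0L) return(character())
  for (x in residues) encode_residues(x)  # validate with our own message
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(residues)))
}

# is `a` compatible with `b` (base sets intersect)? vectorised on codes
.codes_compatible <- function(a, b) bitwAnd(a, b) > 0L

#' Match policies
#'
#' Two symbol-matching policies are used throughout:
#' * `"strict"` — a symbol matches only itself (an `N` in a database sequence
#'   breaks conservation; a signature must be literally invariant).
#' * `"compatible"` — two symbols match when their IUPAC base sets intersect
#'   (an outgroup `N` could hide a true match, so it counts as matching —
#'   conservative for specificity claims; also appropriate for degenerate
#'   primer bases and Sanger consensus ambiguity codes).
#'
#' @param match_policy Character scalar, `"strict"` or `"compatible"`.
#' @return The validated policy string.
#' @export
match_policy <- function(match_policy = c("strict", "compatible")) {
  match.arg(match_policy)
}
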