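# In-silico PCR and signature detection: the computational counterpart of
# amplifying a ~150-bp mini-barcode fragment with a specific primer pair and
# retrieving the signature in the resulting (possibly mixed, degraded)
# consensus sequences. Placement + mismatch counting only: primer
# thermodynamics are out of scope.

#' Construct a primer pair
#'
#' Both primers are written 5'->3': the forward primer in plus-strand sense,
#' the reverse primer in minus-strand sense (as synthesised).
#'
#' @param fwd,rev IUPAC nucleotide strings.
#' @param name Optional pair name.
#' @return A one-row tibble with columns `name`, `fwd`, `rev`.
#' @examples
#' primer_pair("TCATCGAGTCTTTGAACGC", "ATGCGAAGGTCCCCTTTT", name = "MH-1")
#' @export
primer_pair <- function(fwd, rev, name = "primer_pair") {
  stopifnot(is.character(fwd), length(fwd) == 1L, nzchar(fwd),
            is.character(rev), length(rev) == 1L, nzchar(rev))
  fwd <- normalize_residues(fwd)
  rev <- normalize_residues(rev)
  tibble::tibble(name = name, fwd = fwd, rev = rev)
}

# scan one template (residues string) for a primer; returns tibble of
# offset (1-based plus-strand start of the site), strand, mismatches.
# Degenerate primer bases match compatible template bases; the 3'-terminal
# `three_prime_exact` bases must match exactly (zero mismatches there).
.primer_sites_one <- function(residues, primer, max_mismatch, three_prime_exact) {
  p <- encode_residues(primer)
  m <- length(p)
  subj <- encode_residues(residues)
  L <- length(subj)
  k <- min(three_prime_exact, m)
  out <- list()
  for (strand in c("+", "-")) {
    codes <- if (strand == "+") subj else rev(.complement_codes(subj))
    prof <- mismatch_profile(p, codes, policy = "compatible")
    if (length(prof) == 0L) next
    ok <- which(prof <= max_mismatch)
    if (k > 0L && length(ok) > 0L) {
      tail_p <- p[(m - k + 1L):m]
      ok <- ok[vapply(ok, function(o) {
        all(bitwAnd(tail_p, codes[(o + m - k):(o + m - 1L)]) > 0L)
      }, logical(1L))]
    }
    if (length(ok) == 0L) next
    off <- if (strand == "+") ok else L - (ok + m - 1L) + 1L
    out[[strand]] <- tibble::tibble(offset = as.integer(off), strand = strand,
                                    mismatches = as.integer(prof[ok]))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(offset = integer(), strand = character(),
                          mismatches = integer()))
  }
  dplyr::arrange(res, .data$offset, .data$strand)
}

#' Find primer binding sites on templates
#'
#' All placements of a primer on either strand of each template with at most
#' `max_mismatch` mismatches overall and zero mismatches in the primer's
#' 3'-terminal `three_prime_exact` bases (extension requires a matched 3'
#' end). Degenerate primer bases match under compatible IUPAC semantics.
#'
#' @param templates A sequence-set tibble.
#' @param primer A single IUPAC primer string (5'->3').
#' @param max_mismatch Maximum mismatches per site (default 2).
#' @param three_prime_exact Number of 3'-terminal bases that must match
#'   exactly (default 3).
#' @return A tibble with columns `template_id`, `offset` (1-based plus-strand
#'   start of the site), `strand` (`+` if the primer anneals in plus-strand
#'   sense) and `mismatches`, sorted by template then offset.
#' @export
find_primer_sites <- function(templates, primer, max_mismatch = 2L,
                              three_prime_exact = 3L) {
  validate_sequence_set(templates)
  primer <- normalize_residues(primer)
  stopifnot(max_mismatch >= 0L, three_prime_exact >= 0L)
  purrr::map2(templates$id, templates$residues, function(id, res) {
    sites <- .primer_sites_one(res, primer, max_mismatch, three_prime_exact)
    if (nrow(sites) > 0L) dplyr::bind_cols(tibble::tibble(template_id = id), sites)
    else tibble::tibble(template_id = character(), offset = integer(),
                        strand = character(), mismatches = integer())
  }) |> dplyr::bind_rows()
}

#' Predict PCR amplicons from a primer pair
#'
#' Pairs every forward-primer site on the plus strand with every
#' reverse-primer site on the minus strand that lies downstream, and reports
#' the spanned product (primers inclusive) up to `max_product_len`. An empty
#' result means amplification failure.
#'
#' @param templates A sequence-set tibble.
#' @param primers A primer pair tibble from [primer_pair()].
#' @param max_mismatch,three_prime_exact Per-primer site tolerance; see
#'   [find_primer_sites()].
#' @param max_product_len Maximum product length in bp (default 500).
#' @return A tibble with columns `template_id`, `start`, `end` (1-based
#'   inclusive plus-strand coordinates of the product, primers included),
#'   `length`, `residues`, `fwd_mismatches`, `rev_mismatches`.
#' @examples
#' mh <- primer_pair("TCATCGAGTCTTTGAACGC", "ATGCGAAGGTCCCCTTTT")
#' tpl <- sequence_set("t1", paste0(mh$fwd, strrep("A", 113),
#'                                  reverse_complement(mh$rev)), "query")
#' amplify(tpl, mh)
#' @export
amplify <- function(templates, primers, max_mismatch = 2L,
                    three_prime_exact = 3L, max_product_len = 500L) {
  validate_sequence_set(templates)
  stopifnot(is.data.frame(primers), nrow(primers) == 1L,
            all(c("fwd", "rev") %in% names(primers)))
  rev_len <- nchar(primers$rev[[1L]])
  out <- purrr::map2(templates$id, templates$residues, function(id, res) {
    fwd_sites <- .primer_sites_one(res, primers$fwd[[1L]], max_mismatch, three_prime_exact)
    fwd_sites <- fwd_sites[fwd_sites$strand == "+", , drop = FALSE]
    rev_sites <- .primer_sites_one(res, primers$rev[[1L]], max_mismatch, three_prime_exact)
    rev_sites <- rev_sites[rev_sites$strand == "-", , drop = FALSE]
    if (nrow(fwd_sites) == 0L || nrow(rev_sites) == 0L) return(NULL)
    combos <- tidyr::expand_grid(f = seq_len(nrow(fwd_sites)),
                                 r = seq_len(nrow(rev_sites)))
    rows <- purrr::pmap(combos, function(f, r) {
      start <- fwd_sites$offset[[f]]               # fwd primer 5' end
      end <- rev_sites$offset[[r]] + rev_len - 1L  # rev primer 5' end on plus strand
      len <- end - start + 1L
      if (len < 1L || len > max_product_len) return(NULL)
      tibble::tibble(template_id = id, start = start, end = end, length = len,
                     residues = substr(res, start, end),
                     fwd_mismatches = fwd_sites$mismatches[[f]],
                     rev_mismatches = rev_sites$mismatches[[r]])
    })
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(template_id = character(), start = integer(),
                          end = integer(), length = integer(),
                          residues = character(), fwd_mismatches = integer(),
                          rev_mismatches = integer()))
  }
  dplyr::arrange(res, .data$template_id, .data$start, .data$end)
}

#' Detect a signature in query sequences
#'
#' Per query, the best placement of the signature (fewest mismatches; ties
#' broken by smallest plus-strand offset, then `+` before `-`) with at most
#' `max_mismatch` mismatches; otherwise `found = FALSE`. Ambiguity codes in
#' queries (e.g. Sanger consensus codes) match under the default
#' `"compatible"` policy. The default `max_mismatch = 0` makes detection an
#' exact retrieval of the signature.
#'
#' @param queries A sequence-set tibble of query sequences.
#' @param signature A single IUPAC string.
#' @param max_mismatch Maximum tolerated mismatches (default 0).
#' @param both_strands Search the minus strand too (default `TRUE`).
#' @param policy Symbol-matching policy (default `"compatible"`).
#' @return A tibble with one row per query: `query_id`, `found`, `position`
#'   (1-based plus-strand start of the hit, `NA` when not found), `strand`,
#'   `mismatches`.
#' @examples
#' q <- sequence_set("q1", "GTCCGGTCCGCCTCGGCGGTGCG", "query")
#' detect_signature(q, "GTCCGGTCCGCCTCGGCGGTGCG")
#' @export
detect_signature <- function(queries, signature, max_mismatch = 0L,
                             both_strands = TRUE,
                             policy = c("compatible", "strict")) {
  policy <- match.arg(policy)
  validate_sequence_set(queries)
  signature <- normalize_residues(signature)
  s <- encode_residues(signature)
  m <- length(s)
  rows <- purrr::map2(queries$id, queries$residues, function(id, res) {
    subj <- encode_residues(res)
    L <- length(subj)
    best <- NULL  # (mismatches, position, strand)
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      codes <- if (strand == "+") subj else rev(.complement_codes(subj))
      prof <- mismatch_profile(s, codes, policy = policy)
      if (length(prof) == 0L) next
      d <- min(prof)
      if (d > max_mismatch) next
      offs <- which(prof == d)
      pos <- if (strand == "+") offs[1L] else L - (max(offs) + m - 1L) + 1L
      if (is.null(best) || d < best$mm ||
          (d == best$mm && (pos < best$pos || (pos == best$pos && best$strand == "-")))) {
        best <- list(mm = d, pos = as.integer(pos), strand = strand)
      }
    }
    if (is.null(best)) {
      tibble::tibble(query_id = id, found = FALSE, position = NA_integer_,
                     strand = NA_character_, mismatches = NA_integer_)
    } else {
      tibble::tibble(query_id = id, found = TRUE, position = best$pos,
                     strand = best$strand, mismatches = as.integer(best$mm))
    }
  })
  dplyr::bind_rows(rows)
}
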