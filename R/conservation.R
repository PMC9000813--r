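# Alignment-free intragenus conservation.
#
# Conservation of a window is defined as exact substring presence per ingroup
# sequence (not multiple-alignment column identity): the evidence statement
# "no variation in the signature region across the ingroup" is equivalent to
# the window occurring verbatim in every ingroup sequence, and substring
# presence is well-defined for unaligned inputs.

# does `window` occur in `subject` under the given policy? forward strand only
.contains_window <- function(window, subject, policy = "strict") {
  if (policy == "strict") {
    return(grepl(window, subject, fixed = TRUE))
  }
  w <- encode_residues(window)
  vapply(subject, function(s) {
    codes <- encode_residues(s)
    prof <- mismatch_profile(w, codes, policy = "compatible")
    length(prof) > 0L && any(prof == 0L)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Fraction of ingroup sequences containing a window
#'
#' The intragenus-conservation statistic: the fraction of ingroup records in
#' which `window` occurs as an exact forward-strand substring. Under the
#' default `"strict"` policy IUPAC ambiguity symbols match only themselves;
#' under `"compatible"` two symbols match when their base sets intersect.
#'
#' @param ingroup A sequence-set tibble of ingroup records.
#' @param window A single IUPAC nucleotide string.
#' @param policy Symbol-matching policy, `"strict"` (default) or
#'   `"compatible"`. See [match_policy()].
#' @return A fraction in `[0, 1]`.
#' @examples
#' ig <- sequence_set(c("a", "b"), c("TACGT", "ACGACG"), "ingroup")
#' conservation_fraction(ig, "ACG")
#' @export
conservation_fraction <- function(ingroup, window, policy = c("strict", "compatible")) {
  policy <- match.arg(policy)
  validate_sequence_set(ingroup)
  if (nrow(ingroup) == 0L) stop("ingroup is empty: conservation fraction undefined", call. = FALSE)
  stopifnot(is.character(window), length(window) == 1L, nzchar(window))
  mean(.contains_window(window, ingroup$residues, policy = policy))
}

#' Discover maximal conserved regions across an ingroup
#'
#' Scans every ingroup record for windows of length at least `min_len` whose
#' conservation fraction (see [conservation_fraction()]) reaches `threshold`,
#' and returns the *maximal* ones: extending a returned region by one base on
#' either side (where its source record permits) drops the fraction below the
#' threshold, and no returned region is a sub-window of another. Coordinates
#' are reported 1-based inclusive on the first ingroup record containing the
#' region, sorted by start then length.
#'
#' @inheritParams conservation_fraction
#' @param min_len Minimum region length (default 15).
#' @param threshold Required conservation fraction in `(0, 1]`; the standard
#'   criterion is 1.0 (fully conserved). Values below 1 tolerate database
#'   errors and emit a warning.
#' @return A tibble with columns `source_id`, `start`, `end`, `length`,
#'   `residues`, `conservation_fraction` (possibly zero rows).
#' @examples
#' ig <- sequence_set(c("a", "b"), c("AAACGTTT", "GGACGTCC"), "ingroup")
#' find_conserved_regions(ig, min_len = 4)
#' @export
find_conserved_regions <- function(ingroup, min_len = 15L, threshold = 1,
                                   policy = c("strict", "compatible")) {
  policy <- match.arg(policy)
  validate_sequence_set(ingroup)
  stopifnot(min_len >= 1L, threshold > 0, threshold <= 1)
  if (nrow(ingroup) == 0L) stop("ingroup is empty", call. = FALSE)
  if (threshold < 1) {
    warning("conservation threshold below 1: regions may vary within the ingroup",
            call. = FALSE)
  }

  frac <- function(w) mean(.contains_window(w, ingroup$residues, policy = policy))

  # two-pointer maximal-window scan per reference record; valid because the
  # fraction is anti-monotone under window extension
  found <- character()
  for (r in seq_len(nrow(ingroup))) {
    ref <- ingroup$residues[[r]]
    n <- nchar(ref)
    e <- 0L  # inclusive end of the current maximal window
    prev_e <- 0L
    for (s in seq_len(n)) {
      if (e < s - 1L) e <- s - 1L
      while (e < n && frac(substr(ref, s, e + 1L)) >= threshold) e <- e + 1L
      if (e - s + 1L >= min_len && e > prev_e) {
        found <- c(found, substr(ref, s, e))
      }
      prev_e <- max(prev_e, e)
    }
  }
  found <- unique(found)
  # drop regions contained in another returned region
  if (length(found) > 1L) {
    keep <- vapply(seq_along(found), function(i) {
      !any(vapply(seq_along(found)[-i], function(j) {
        nchar(found[[j]]) > nchar(found[[i]]) && grepl(found[[i]], found[[j]], fixed = TRUE)
      }, logical(1L)))
    }, logical(1L))
    found <- found[keep]
  }
  if (length(found) == 0L) {
    return(tibble::tibble(source_id = character(), start = integer(),
                          end = integer(), length = integer(),
                          residues = character(), conservation_fraction = double()))
  }
  # locate each region on the first record containing it
  loc <- purrr::map(found, function(w) {
    for (r in seq_len(nrow(ingroup))) {
      hit <- if (policy == "strict") {
        as.integer(regexpr(w, ingroup$residues[[r]], fixed = TRUE))
      } else {
        codes <- encode_residues(ingroup$residues[[r]])
        prof <- mismatch_profile(encode_residues(w), codes, policy = "compatible")
        if (length(prof) > 0L && any(prof == 0L)) which(prof == 0L)[1L] else -1L
      }
      if (hit > 0L) {
        return(list(source_index = r, source_id = ingroup$id[[r]], start = hit))
      }
    }
    stop("internal error: conserved region not found in any record")  # nocov
  })
  out <- tibble::tibble(
    source_index = purrr::map_int(loc, "source_index"),
    source_id = purrr::map_chr(loc, "source_id"),
    start = purrr::map_int(loc, ~ as.integer(.x$start)),
    length = nchar(found),
    residues = found,
    conservation_fraction = purrr::map_dbl(found, frac)
  )
  out$end <- out$start + out$length - 1L
  out <- dplyr::arrange(out, .data$source_index, .data$start, .data$length)
  dplyr::select(out, "source_id", "start", "end", "length", "residues",
                "conservation_fraction")
}
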