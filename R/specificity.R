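# Intergeneric specificity: how far a candidate window is from its closest
# match in the outgroup. This replaces a database BLAST screen with exact
# local scoring against a user-supplied outgroup set: inputs are desk-scale,
# so no heuristic seeding is needed.

# Per-offset mismatch counts of `window` codes against `subject` codes
# (both integer bitmask vectors). Returns integer(0) when the subject is
# shorter than the window.
mismatch_profile <- function(window, subject, policy = "strict") {
  m <- length(window)
  L <- length(subject)
  noff <- L - m + 1L
  if (noff < 1L) return(integer(0))
  acc <- integer(noff)
  if (policy == "strict") {
    for (i in seq_len(m)) {
      acc <- acc + (window[[i]] != subject[i:(i + noff - 1L)])
    }
  } else {
    for (i in seq_len(m)) {
      acc <- acc + (bitwAnd(window[[i]], subject[i:(i + noff - 1L)]) == 0L)
    }
  }
  acc
}

# Infix (semi-global) unit-cost edit distance of `window` against any
# substring of `subject`; row-vectorised DP. Returns list(distance, end)
# where `end` is the 1-based subject position of the best match end.
edit_infix_distance <- function(window, subject, policy = "strict") {
  m <- length(window)
  L <- length(subject)
  if (L == 0L) return(list(distance = m, end = 0L))
  prev <- rep(0L, L + 1L)  # D[0, j] = 0: free start in subject
  jidx <- seq_len(L + 1L)
  for (i in seq_len(m)) {
    if (policy == "strict") {
      cost <- as.integer(window[[i]] != subject)
    } else {
      cost <- as.integer(bitwAnd(window[[i]], subject) == 0L)
    }
    tmp <- pmin(prev[-1L] + 1L, prev[-(L + 1L)] + cost)  # deletion / diagonal
    cur <- c(i, tmp)
    # horizontal (insertion) pass: cur[j] = min_k<=j (cur[k] + (j - k))
    cur <- cummin(cur - jidx) + jidx
    prev <- cur
  }
  d <- min(prev[-1L])
  list(distance = as.integer(d), end = which(prev[-1L] == d)[1L])
}

#' Specificity policy
#'
#' Bundles the parameters of the outgroup-distance criterion: a window is
#' *specific* when its minimum distance to every outgroup window is at least
#' `d_min` variations (the "at least one variation from every non-target
#' sequence" rule corresponds to `d_min = 1`).
#'
#' @param d_min Minimum required distance (integer >= 1, default 1).
#' @param metric `"hamming"` (default): minimum per-position mismatch count
#'   over all full-length placements of the window; preserves monotonicity in
#'   window length. `"edit"`: minimum infix (semi-global) edit distance, for
#'   indel-containing outgroups.
#' @param both_strands Search the reverse complement of each outgroup record
#'   too (default `TRUE`; database sequences have arbitrary orientation).
#' @param match_policy Symbol-matching policy for ambiguity codes; default
#'   `"compatible"` (an outgroup `N` could hide a match, so it counts as one —
#'   conservative for specificity claims).
#' @return A list with class `"specificity_policy"`.
#' @export
specificity_policy <- function(d_min = 1L, metric = c("hamming", "edit"),
                               both_strands = TRUE,
                               match_policy = c("compatible", "strict")) {
  metric <- match.arg(metric)
  match_policy <- match.arg(match_policy)
  stopifnot(is.numeric(d_min), length(d_min) == 1L, d_min >= 1)
  structure(
    list(d_min = as.integer(d_min), metric = metric,
         both_strands = isTRUE(both_strands), match_policy = match_policy),
    class = "specificity_policy"
  )
}

#' Minimum distance of a window to an outgroup set
#'
#' Scores a candidate window against every outgroup record: under the
#' `"hamming"` metric, the minimum per-position mismatch count over all
#' full-length placements of the window inside each record (both strands by
#' default); under `"edit"`, the minimum infix edit distance to any
#' substring. Records shorter than the window contribute `Inf` (no
#' overhanging placements are considered). The minimizing record, 1-based
#' plus-strand offset and strand are reported; ties are broken by record
#' order, then smallest offset, then `+` before `-`.
#'
#' @param outgroup A sequence-set tibble of outgroup records.
#' @param window A single IUPAC nucleotide string.
#' @param policy A [specificity_policy()].
#' @param .stop_at Internal early-exit bound: scanning stops once a distance
#'   `<= .stop_at` has been seen (the reported minimum is then exact only in
#'   its being `<= .stop_at`). Default `-1` (exhaustive).
#' @return A one-row tibble: `window`, `length`, `min_distance`,
#'   `nearest_outgroup_id`, `nearest_offset`, `nearest_strand`.
#'   `min_distance` is `Inf` when the outgroup is empty (with a warning) or
#'   no record is at least as long as the window.
#' @examples
#' og <- sequence_set("o1", "GGACGTCC", "outgroup")
#' min_outgroup_distance(og, "ACGT")
#' @export
min_outgroup_distance <- function(outgroup, window, policy = specificity_policy(),
                                  .stop_at = -1L) {
  stopifnot(inherits(policy, "specificity_policy"),
            is.character(window), length(window) == 1L, nzchar(window))
  validate_sequence_set(outgroup)
  res <- list(min_distance = Inf, id = NA_character_, offset = NA_integer_,
              strand = NA_character_)
  if (nrow(outgroup) == 0L) {
    warning("empty outgroup: window is trivially specific", call. = FALSE)
  } else {
    w <- encode_residues(window)
    m <- length(w)
    for (r in seq_len(nrow(outgroup))) {
      subj <- encode_residues(outgroup$residues[[r]])
      L <- length(subj)
      strands <- if (policy$both_strands) c("+", "-") else "+"
      # best placement within this record, ordered by (distance, plus-strand
      # offset, '+' before '-')
      rec <- list(min_distance = Inf, offset = NA_integer_, strand = NA_character_)
      for (strand in strands) {
        codes <- if (strand == "+") subj else rev(.complement_codes(subj))
        if (policy$metric == "hamming") {
          prof <- mismatch_profile(w, codes, policy = policy$match_policy)
          if (length(prof) == 0L) next
          d <- min(prof)
          # report the plus-strand coordinate of the leftmost minimizer
          offs <- which(prof == d)
          off <- if (strand == "+") offs[1L] else L - (max(offs) + m - 1L) + 1L
        } else {
          hit <- edit_infix_distance(w, codes, policy = policy$match_policy)
          d <- hit$distance
          off <- if (strand == "+") max(1L, hit$end - m + 1L) else max(1L, L - hit$end + 1L)
        }
        if (d < rec$min_distance ||
            (d == rec$min_distance && (off < rec$offset ||
                                       (off == rec$offset && rec$strand == "-")))) {
          rec <- list(min_distance = d, offset = as.integer(off), strand = strand)
        }
      }
      if (rec$min_distance < res$min_distance) {
        res <- list(min_distance = rec$min_distance, id = outgroup$id[[r]],
                    offset = rec$offset, strand = rec$strand)
      }
      if (res$min_distance <= .stop_at) break
    }
  }
  tibble::tibble(
    window = window, length = nchar(window),
    min_distance = as.double(res$min_distance),
    nearest_outgroup_id = res$id,
    nearest_offset = res$offset,
    nearest_strand = res$strand
  )
}

# complement (not reversed) of an encoded vector: bit-reverse the 4-bit mask
.complement_codes <- local({
  comp <- integer(15L)
  for (b in 1:15) {
    comp[[b]] <- bitwOr(bitwOr(ifelse(bitwAnd(b, 1L) > 0L, 8L, 0L),
                               ifelse(bitwAnd(b, 2L) > 0L, 4L, 0L)),
                        bitwOr(ifelse(bitwAnd(b, 4L) > 0L, 2L, 0L),
                               ifelse(bitwAnd(b, 8L) > 0L, 1L, 0L)))
  }
  function(codes) comp[codes]
})

#' Is a window specific against an outgroup?
#'
#' `TRUE` when the minimum outgroup distance (see [min_outgroup_distance()])
#' is at least `policy$d_min`. An empty outgroup is vacuously specific (with
#' a warning).
#'
#' @inheritParams min_outgroup_distance
#' @return A logical scalar.
#' @export
is_specific <- function(outgroup, window, policy = specificity_policy()) {
  score <- min_outgroup_distance(outgroup, window, policy,
                                 .stop_at = policy$d_min - 1L)
  score$min_distance >= policy$d_min
}
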