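# The length sweep: evaluate candidate windows of decreasing length and
# select the minimal window that is both ingroup-conserved and
# outgroup-specific. Two monotonicity facts make the search exact and fast:
#   * conservation is anti-monotone in window length (a sub-window of a
#     conserved window is conserved), so searching inside maximal conserved
#     regions is complete;
#   * Hamming specificity is monotone non-decreasing in window length (a
#     superstring is at least as far from the outgroup as the window it
#     contains), so per anchor the smallest specific length is found by
#     binary search.

#' Evaluate candidate windows against ingroup and outgroup
#'
#' One row per window, order preserved: its conservation fraction and
#' conserved verdict (fraction `>= threshold`), and its minimum outgroup
#' distance and specific verdict (distance `>= policy$d_min`). This is the
#' machine form of a candidate-table row (sequence / length / intergeneric
#' specificity / intragenus conservation).
#'
#' @param windows Candidate windows: a character vector of IUPAC strings, or
#'   a data frame with a `residues` column (extra columns are carried along).
#' @param ingroup,outgroup Sequence-set tibbles.
#' @param policy A [specificity_policy()].
#' @param threshold Conservation threshold (default 1.0).
#' @param conservation_policy Symbol-matching policy for the conservation
#'   side, `"strict"` by default (a signature must be literally invariant).
#' @return A tibble with columns `residues`, `length`,
#'   `conservation_fraction`, `conserved`, `min_distance`,
#'   `nearest_outgroup_id`, `nearest_offset`, `nearest_strand`, `specific`.
#' @examples
#' ig <- sequence_set(c("a", "b"), c("TTACGGA", "CACGGTT"), "ingroup")
#' og <- sequence_set("o", "TTTTTTTT", "outgroup")
#' evaluate_candidates(c("ACGG", "ACGGA"), ig, og)
#' @export
evaluate_candidates <- function(windows, ingroup, outgroup,
                                policy = specificity_policy(), threshold = 1,
                                conservation_policy = c("strict", "compatible")) {
  conservation_policy <- match.arg(conservation_policy)
  extra <- NULL
  if (is.data.frame(windows)) {
    stopifnot("residues" %in% names(windows))
    extra <- dplyr::select(windows, -dplyr::any_of(
      c("residues", "length", "conservation_fraction", "conserved",
        "min_distance", "nearest_outgroup_id", "nearest_offset",
        "nearest_strand", "specific")))
    windows <- windows$residues
  }
  stopifnot(is.character(windows), length(windows) > 0L)
  rows <- purrr::map(windows, function(w) {
    cf <- conservation_fraction(ingroup, w, policy = conservation_policy)
    sc <- min_outgroup_distance(outgroup, w, policy)
    tibble::tibble(
      residues = w, length = nchar(w),
      conservation_fraction = cf, conserved = cf >= threshold,
      min_distance = sc$min_distance,
      nearest_outgroup_id = sc$nearest_outgroup_id,
      nearest_offset = sc$nearest_offset,
      nearest_strand = sc$nearest_strand,
      specific = sc$min_distance >= policy$d_min
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(extra) && ncol(extra) > 0L) out <- dplyr::bind_cols(extra, out)
  out
}

#' Sweep sub-windows of a conserved region across lengths
#'
#' In explicit-lengths mode evaluates, for each requested length, every
#' sub-window of the region at that length; with `lengths = NULL` (all
#' sub-windows mode) every sub-window with length in
#' `[min_len, nchar(region)]`. Results are grouped by length in descending
#' order (longest first), then by start.
#'
#' @param region A region: a single IUPAC string or a one-row data frame with
#'   a `residues` column (e.g. one row of [find_conserved_regions()] output).
#' @param ingroup,outgroup Sequence-set tibbles.
#' @param lengths Integer vector of window lengths, or `NULL` for all
#'   sub-windows of length at least `min_len`.
#' @param min_len Minimum length in all-sub-windows mode (default 15).
#' @inheritParams evaluate_candidates
#' @return An evaluation tibble (see [evaluate_candidates()]) with additional
#'   columns `start` (1-based offset of the sub-window within the region).
#' @export
sweep_lengths <- function(region, ingroup, outgroup, lengths = NULL,
                          min_len = 15L, policy = specificity_policy(),
                          threshold = 1,
                          conservation_policy = c("strict", "compatible")) {
  conservation_policy <- match.arg(conservation_policy)
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L, "residues" %in% names(region))
    region <- region$residues[[1L]]
  }
  stopifnot(is.character(region), length(region) == 1L, nzchar(region))
  n <- nchar(region)
  if (is.null(lengths)) {
    stopifnot(min_len >= 1L, min_len <= n)
    lengths <- seq.int(min_len, n)
  }
  lengths <- as.integer(lengths)
  if (any(lengths > n)) {
    stop("requested length ", max(lengths), " exceeds region length ", n, call. = FALSE)
  }
  stopifnot(all(lengths >= 1L))
  grid <- dplyr::bind_rows(purrr::map(sort(unique(lengths), decreasing = TRUE),
    function(L) tibble::tibble(start = seq_len(n - L + 1L),
                               residues = substring(region, seq_len(n - L + 1L),
                                                    seq_len(n - L + 1L) + L - 1L))))
  evaluate_candidates(grid, ingroup, outgroup, policy = policy,
                      threshold = threshold,
                      conservation_policy = conservation_policy)
}

#' Mine the minimal diagnostic signature
#'
#' Returns the shortest window, with length in `[min_len, max_len]`, that is
#' conserved across the ingroup at `threshold` and at least `policy$d_min`
#' variations away from every outgroup window. The search runs inside maximal
#' conserved regions only (complete, because conservation is anti-monotone in
#' length) and, under the Hamming metric, finds the smallest specific length
#' per anchor by binary search (specificity is monotone in length); the edit
#' metric falls back to a linear scan. Ties among equal-length winners are
#' broken by leftmost start in the earliest conserved region. If no window
#' qualifies the result is empty but carries the full evaluation audit.
#'
#' @param ingroup,outgroup Sequence-set tibbles.
#' @param policy A [specificity_policy()].
#' @param threshold Conservation threshold (default 1.0).
#' @param min_len,max_len Window length bounds (defaults 15 and 55: the
#'   practical mini-barcode range — longer windows stop being conserved,
#'   shorter ones stop being specific).
#' @param conservation_policy Matching policy for conservation
#'   (default `"strict"`).
#' @return A `signature_result` object: a list with elements `signature`
#'   (one-row tibble, or `NULL` if nothing qualifies), `evaluations` (audit
#'   tibble of every window examined), `regions` (the conserved regions
#'   searched) and `parameters`. Supports [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @examples
#' ig <- sequence_set(c("a", "b"), c("AAACGTTT", "GGACGTCC"), "ingroup")
#' og <- sequence_set("o", "TTTTAGGGG", "outgroup")
#' mine_signature(ig, og, min_len = 2, max_len = 8)
#' @export
mine_signature <- function(ingroup, outgroup, policy = specificity_policy(),
                           threshold = 1, min_len = 15L, max_len = 55L,
                           conservation_policy = c("strict", "compatible")) {
  conservation_policy <- match.arg(conservation_policy)
  validate_sequence_set(ingroup)
  validate_sequence_set(outgroup)
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  stopifnot(min_len >= 1L, max_len >= min_len)
  if (nrow(ingroup) == 0L) stop("ingroup is empty", call. = FALSE)

  params <- list(policy = policy, threshold = threshold, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 conservation_policy = conservation_policy)
  regions <- find_conserved_regions(ingroup, min_len = min_len,
                                    threshold = threshold,
                                    policy = conservation_policy)
  empty_eval <- tibble::tibble(
    residues = character(), length = integer(),
    conservation_fraction = double(), conserved = logical(),
    min_distance = double(), nearest_outgroup_id = character(),
    nearest_offset = integer(), nearest_strand = character(),
    specific = logical(), start = integer(), region_id = character())
  if (nrow(regions) == 0L) {
    return(new_signature_result(NULL, empty_eval, regions, params))
  }

  if (nrow(outgroup) == 0L) {
    warning("empty outgroup: returning the shortest conserved window ",
            "(vacuous specificity)", call. = FALSE)
    w <- substr(regions$residues[[1L]], 1L, min_len)
    sig <- tibble::tibble(
      residues = w, length = nchar(w),
      source_id = regions$source_id[[1L]], start = regions$start[[1L]],
      end = regions$start[[1L]] + nchar(w) - 1L,
      conservation_fraction = conservation_fraction(ingroup, w, conservation_policy),
      min_distance = Inf
    )
    return(new_signature_result(sig, empty_eval, regions, params))
  }

  evals <- list()
  eval_window <- function(w, start, region_row, stop_at = -1L) {
    cf <- conservation_fraction(ingroup, w, policy = conservation_policy)
    sc <- min_outgroup_distance(outgroup, w, policy, .stop_at = stop_at)
    row <- tibble::tibble(
      residues = w, length = nchar(w),
      conservation_fraction = cf, conserved = cf >= threshold,
      min_distance = sc$min_distance,
      nearest_outgroup_id = sc$nearest_outgroup_id,
      nearest_offset = sc$nearest_offset,
      nearest_strand = sc$nearest_strand,
      specific = sc$min_distance >= policy$d_min,
      start = as.integer(start),
      region_id = paste0(region_row$source_id, ":", region_row$start, "-", region_row$end)
    )
    evals[[length(evals) + 1L]] <<- row
    row
  }

  best <- NULL  # list(length, region_index, start, residues, region_row)
  for (ri in seq_len(nrow(regions))) {
    reg <- regions[ri, ]
    rlen <- reg$length
    if (rlen < min_len) next
    for (a in seq_len(rlen - min_len + 1L)) {
      cap <- min(max_len, rlen - a + 1L)
      if (!is.null(best)) cap <- min(cap, best$length - 1L)
      if (cap < min_len) next
      window_at <- function(L) substr(reg$residues, a, a + L - 1L)
      if (policy$metric == "hamming") {
        # feasibility probe at the cap, then binary search for the smallest
        # specific length (specificity is monotone in length)
        top <- eval_window(window_at(cap), a, reg, stop_at = policy$d_min - 1L)
        if (!top$specific) next
        lo <- min_len; hi <- cap
        while (lo < hi) {
          mid <- (lo + hi) %/% 2L
          probe <- eval_window(window_at(mid), a, reg, stop_at = policy$d_min - 1L)
          if (probe$specific) hi <- mid else lo <- mid + 1L
        }
        found_len <- lo
      } else {
        found_len <- NA_integer_
        for (L in seq.int(min_len, cap)) {
          probe <- eval_window(window_at(L), a, reg, stop_at = policy$d_min - 1L)
          if (probe$specific) { found_len <- L; break }
        }
        if (is.na(found_len)) next
      }
      if (is.null(best) || found_len < best$length) {
        best <- list(length = found_len, region_index = ri, start = a,
                     residues = window_at(found_len), region_row = reg)
        if (best$length == min_len) break  # nothing shorter is possible
      }
    }
    if (!is.null(best) && best$length == min_len) break
  }

  evaluations <- if (length(evals) > 0L) dplyr::bind_rows(evals) else empty_eval
  if (is.null(best)) {
    return(new_signature_result(NULL, evaluations, regions, params))
  }
  # re-score the winner exhaustively for an exact reported distance
  final <- min_outgroup_distance(outgroup, best$residues, policy)
  sig <- tibble::tibble(
    residues = best$residues, length = best$length,
    source_id = best$region_row$source_id,
    start = best$region_row$start + best$start - 1L,
    end = best$region_row$start + best$start - 1L + best$length - 1L,
    conservation_fraction = conservation_fraction(ingroup, best$residues,
                                                  conservation_policy),
    min_distance = final$min_distance,
    nearest_outgroup_id = final$nearest_outgroup_id,
    nearest_strand = final$nearest_strand
  )
  new_signature_result(sig, evaluations, regions, params)
}

new_signature_result <- function(signature, evaluations, regions, parameters) {
  structure(
    list(signature = signature, evaluations = evaluations,
         regions = regions, parameters = parameters),
    class = "signature_result"
  )
}

#' Select the signature from an evaluated candidate table
#'
#' Applies the selection rule — the shortest candidate whose conservation and
#' specificity verdicts are both positive — to a table of evaluated
#' candidates (for example the output of [evaluate_candidates()] or a
#' hand-entered candidate table with `conserved` and `specific` flag
#' columns). Ties are broken by table order.
#'
#' @param evaluations A data frame with columns `residues`, `length` (or
#'   computable from `residues`), `conserved`, `specific`.
#' @return A one-row tibble (the winner), or a zero-row tibble when no
#'   candidate has both flags.
#' @export
select_signature <- function(evaluations) {
  stopifnot(is.data.frame(evaluations),
            all(c("residues", "conserved", "specific") %in% names(evaluations)))
  ev <- tibble::as_tibble(evaluations)
  if (!"length" %in% names(ev)) ev$length <- nchar(ev$residues)
  hits <- ev[ev$conserved & ev$specific, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  hits[order(hits$length)[1L], , drop = FALSE]
}

#' @export
print.signature_result <- function(x, ...) {
  cat("<signature_result>\n")
  p <- x$parameters
  cat(sprintf("  criteria: conservation >= %g (%s), distance >= %d (%s%s)\n",
              p$threshold, p$conservation_policy, p$policy$d_min, p$policy$metric,
              if (p$policy$both_strands) ", both strands" else ""))
  cat(sprintf("  searched: %d conserved region(s), %d window evaluation(s)\n",
              nrow(x$regions), nrow(x$evaluations)))
  if (is.null(x$signature) || nrow(x$signature) == 0L) {
    cat("  signature: none found\n")
  } else {
    s <- x$signature
    cat(sprintf("  signature: %s (%d bp)\n", s$residues, s$length))
    cat(sprintf("  location: %s:%d-%d  conservation %.3f  min outgroup distance %s\n",
                s$source_id, s$start, s$end, s$conservation_fraction,
                format(s$min_distance)))
  }
  invisible(x)
}
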