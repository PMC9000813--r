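# Seeded generators of ingroup/outgroup/query sets with planted ground
# truth, so every stage of the pipeline is testable without downloads. The
# generators emulate the structure that matters for signature mining — a
# block exactly conserved across the ingroup, an outgroup in which short
# windows still match but longer ones do not, and mixed degraded query
# fragments — not a molecular-evolution model (no transition/transversion
# bias, no rate heterogeneity). Generated residues use {A,C,G,T} only.

.bases <- c("A", "C", "G", "T")

.random_bases <- function(n) paste(sample(.bases, n, replace = TRUE), collapse = "")

# substitute position `pos` of `x` with a random base different from the
# current one; returns list(residues, from, to)
.substitute_base <- function(x, pos) {
  from <- substr(x, pos, pos)
  to <- sample(setdiff(.bases, from), 1L)
  substr(x, pos, pos) <- to
  list(residues = x, from = from, to = to)
}

#' Generate a synthetic ingroup with a planted conserved core
#'
#' Each record is `random flank + core + random flank`: the flanks derive
#' from a shared ancestor flank independently mutated at `flank_mut_rate`
#' per site, while the core is never mutated, so
#' `conservation_fraction(set, core) == 1` by construction. The flank bases
#' immediately adjacent to the core are forced to differ across records
#' (rotating bases, recorded in the mutation log) so that the planted core is
#' exactly the maximal conserved block for `n >= 2` — without the guard, a
#' junction base can survive unmutated in every record and extend the
#' conserved block by chance.
#'
#' @param n Number of ingroup records (>= 1).
#' @param core The planted core (IUPAC string; `{A,C,G,T}` recommended).
#' @param flank_len Length of each flank (default 60).
#' @param flank_mut_rate Per-site substitution probability in the flanks
#'   (default 0.3).
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return A list with elements `sequences` (an ingroup sequence-set tibble;
#'   the core starts at `flank_len + 1` in every record) and `truth` (planted
#'   core, per-record mutation log, seed).
#' @export
generate_ingroup <- function(n, core, flank_len = 60L, flank_mut_rate = 0.3,
                             seed = 1L) {
  stopifnot(n >= 1L, flank_len >= 0L,
            flank_mut_rate >= 0, flank_mut_rate <= 1)
  n <- as.integer(n)
  flank_len <- as.integer(flank_len)
  core <- normalize_residues(core)
  withr::with_seed(seed, {
    anc_left <- .random_bases(flank_len)
    anc_right <- .random_bases(flank_len)
    recs <- vector("list", n)
    logs <- vector("list", n)
    for (i in seq_len(n)) {
      log <- list()
      mutate_flank <- function(flank, offset0) {
        if (nchar(flank) == 0L) return(flank)
        hit <- which(stats::runif(nchar(flank)) < flank_mut_rate)
        for (pos in hit) {
          s <- .substitute_base(flank, pos)
          flank <- s$residues
          log[[length(log) + 1L]] <<- tibble::tibble(
            position = offset0 + pos, from = s$from, to = s$to)
        }
        flank
      }
      left <- mutate_flank(anc_left, 0L)
      right <- mutate_flank(anc_right, flank_len + nchar(core))
      # junction guard: adjacent flank bases rotate across records
      if (flank_len > 0L) {
        force_base <- function(flank, pos, base, offset0) {
          if (substr(flank, pos, pos) != base) {
            log[[length(log) + 1L]] <<- tibble::tibble(
              position = offset0 + pos, from = substr(flank, pos, pos), to = base)
            substr(flank, pos, pos) <- base
          }
          flank
        }
        left <- force_base(left, flank_len, .bases[(i - 1L) %% 4L + 1L], 0L)
        right <- force_base(right, 1L, .bases[i %% 4L + 1L],
                            flank_len + nchar(core))
      }
      recs[[i]] <- paste0(left, core, right)
      logs[[i]] <- if (length(log) > 0L) dplyr::bind_rows(log) else
        tibble::tibble(position = integer(), from = character(), to = character())
    }
    ids <- sprintf("ig%03d", seq_len(n))
    seqs <- sequence_set(ids, unlist(recs), group = "ingroup",
                         taxon = "synthetic ingroup")
    # independent re-check, not trusted from construction
    stopifnot(all(grepl(core, seqs$residues, fixed = TRUE)))
    names(logs) <- ids
    list(sequences = seqs,
         truth = list(planted_core = core, core_start = flank_len + 1L,
                      mutation_log = logs, seed = seed))
  })
}

#' Generate a synthetic outgroup with a planted minimal signature length
#'
#' Constructs an outgroup in which the shortest core sub-window that is
#' specific (Hamming distance >= 1 from every outgroup window) has length
#' exactly `period`. One outgroup record carries `period` phase-shifted
#' substituted copies of the core, copy `j` substituted at every core
#' position congruent to `j` modulo `period` (substituted bases differ from
#' the original): every window of the core shorter than `period` misses at
#' least one residue class and therefore occurs *exactly* in the copy whose
#' substituted class it avoids, while every window of length `period` or more
#' covers all classes and is substituted in every copy. `n_decoys` unrelated
#' random records are added. After generation the guarantee is re-checked by
#' independent brute-force scanning — every core window shorter than
#' `period` occurs exactly somewhere in the outgroup (so no shorter window
#' can be specific) and at least one `period`-length core window occurs
#' nowhere on either strand (so length `period` is achievable) — with
#' spacers and decoys resampled on a chance collision.
#'
#' @param core The planted core (`{A,C,G,T}` only; length <= 100 so the
#'   brute-force verification stays exact and cheap).
#' @param period Planted minimal specific length, in `[4, nchar(core)]`
#'   (periods below 4 are rejected: decoy collisions would make the planted
#'   minimum unreliable).
#' @param n_decoys Number of unrelated random records (default 3).
#' @param decoy_len Length of each decoy (default `max(60, nchar(core))`).
#' @param seed Integer seed.
#' @return A list with elements `sequences` (an outgroup sequence-set
#'   tibble) and `truth` (core, period, per-copy substitution log, seed).
#' @export
generate_outgroup <- function(core, period, n_decoys = 3L,
                              decoy_len = NULL, seed = 1L) {
  core <- normalize_residues(core)
  n <- nchar(core)
  stopifnot(n <= 100L, grepl("^[ACGT]+$", core))
  if (period < 4L || period > n) {
    stop("period must be in [4, nchar(core)] (got ", period, ")", call. = FALSE)
  }
  period <- as.integer(period)
  if (is.null(decoy_len)) decoy_len <- max(60L, n)
  kmers <- function(k) unique(substring(core, seq_len(n - k + 1L),
                                        seq_len(n - k + 1L) + k - 1L))
  withr::with_seed(seed, {
    for (attempt in seq_len(25L)) {
      sub_log <- vector("list", period)
      copies <- character(period)
      for (j in seq_len(period)) {
        x <- core
        pos <- seq.int(j, n, by = period)
        entries <- purrr::map(pos, function(q) {
          s <- .substitute_base(x, q)
          x <<- s$residues
          tibble::tibble(position = q, from = s$from, to = s$to)
        })
        copies[[j]] <- x
        sub_log[[j]] <- dplyr::bind_rows(entries)
      }
      spacer_len <- max(10L, period)
      spacers <- vapply(seq_len(period + 1L), function(i) .random_bases(spacer_len),
                        character(1L))
      carrier <- paste0(spacers[1L],
                        paste0(copies, spacers[-1L], collapse = ""))
      decoys <- vapply(seq_len(n_decoys), function(i) .random_bases(decoy_len),
                       character(1L))
      ids <- c("og_core", if (n_decoys > 0L) sprintf("og_decoy%02d", seq_len(n_decoys)))
      seqs <- sequence_set(ids, c(carrier, decoys), group = "outgroup",
                           taxon = "synthetic outgroup")
      # brute-force verification of the planted guarantee: every core window
      # shorter than `period` occurs exactly (hence is non-specific), and at
      # least one core window of length `period` occurs nowhere on either
      # strand (hence length `period` is achievable)
      all_res <- c(seqs$residues, reverse_complement(seqs$residues))
      p_absent <- any(vapply(kmers(period), function(w) {
        !any(grepl(w, all_res, fixed = TRUE))
      }, logical(1L)))
      pm1_present <- all(vapply(kmers(period - 1L), function(w) {
        any(grepl(w, seqs$residues, fixed = TRUE))
      }, logical(1L)))
      if (p_absent && pm1_present) {
        names(sub_log) <- sprintf("copy%02d", seq_len(period))
        return(list(sequences = seqs,
                    truth = list(planted_core = core, period = period,
                                 substitution_log = sub_log, seed = seed)))
      }
    }
  })
  stop("could not generate a collision-free outgroup after 25 attempts; ",
       "try a different seed or a longer core", call. = FALSE)
}

#' Generate synthetic mixture queries (compound-preparation scenario)
#'
#' Emulates detection in manufactured multi-herb preparations with degraded
#' DNA: each batch is a set of short fragments, exactly one of which embeds
#' the signature (unless `plant = FALSE`, the negative control), among
#' `n_nontarget` unrelated random fragments. The target fragment's flanks may
#' be truncated (degradation) but the signature itself is never truncated;
#' fragment orientation is random (detection must search both strands).
#'
#' @param n_batches Number of batches (default 7).
#' @param signature The signature to plant (IUPAC string).
#' @param signature_fragment Optional carrier fragment containing
#'   `signature`; by default a fragment of length ~150 is built as
#'   `random pad + signature + random pad`.
#' @param n_nontarget Unrelated fragments per batch (default 5).
#' @param fragment_len_range Length range of non-target fragments, within
#'   `[50, 500]` (default `c(80, 200)`).
#' @param degrade Degradation intensity in `[0, 1)`: up to this fraction of
#'   each flank of the target fragment is truncated (default 0.3).
#' @param plant Plant the signature fragment? `FALSE` gives the negative
#'   control (no batch contains the signature).
#' @param seed Integer seed.
#' @return A list with elements `sequences` (a query sequence-set tibble
#'   with an extra `batch` column) and `truth` (per-batch carrier record id,
#'   or `NA` for negative controls).
#' @export
generate_mixture_queries <- function(n_batches = 7L, signature,
                                     signature_fragment = NULL,
                                     n_nontarget = 5L,
                                     fragment_len_range = c(80L, 200L),
                                     degrade = 0.3, plant = TRUE, seed = 1L) {
  signature <- normalize_residues(signature)
  stopifnot(n_batches >= 1L, n_nontarget >= 0L,
            length(fragment_len_range) == 2L,
            fragment_len_range[1L] >= 50L, fragment_len_range[2L] <= 500L,
            fragment_len_range[1L] <= fragment_len_range[2L],
            degrade >= 0, degrade < 1)
  sig_rc <- reverse_complement(signature)
  contains_sig <- function(x) grepl(signature, x, fixed = TRUE) ||
    grepl(sig_rc, x, fixed = TRUE)
  withr::with_seed(seed, {
    if (is.null(signature_fragment)) {
      pad <- max(0L, (150L - nchar(signature)) %/% 2L)
      signature_fragment <- paste0(.random_bases(pad), signature, .random_bases(pad))
    } else {
      signature_fragment <- normalize_residues(signature_fragment)
      if (!grepl(signature, signature_fragment, fixed = TRUE)) {
        stop("signature_fragment does not contain the signature", call. = FALSE)
      }
    }
    sig_at <- as.integer(regexpr(signature, signature_fragment, fixed = TRUE))
    left_flank <- sig_at - 1L
    right_flank <- nchar(signature_fragment) - (sig_at + nchar(signature) - 1L)
    rows <- list()
    truth <- character(n_batches)
    for (b in seq_len(n_batches)) {
      frags <- character()
      for (k in seq_len(n_nontarget)) {
        lens <- seq.int(fragment_len_range[1L], fragment_len_range[2L])
        repeat {
          f <- .random_bases(lens[sample.int(length(lens), 1L)])
          if (!contains_sig(f)) break  # never an accidental positive
        }
        frags <- c(frags, f)
      }
      carrier_idx <- NA_integer_
      if (plant) {
        lt <- if (left_flank > 0L) sample.int(floor(degrade * left_flank) + 1L, 1L) - 1L else 0L
        rt <- if (right_flank > 0L) sample.int(floor(degrade * right_flank) + 1L, 1L) - 1L else 0L
        target <- substr(signature_fragment, 1L + lt,
                         nchar(signature_fragment) - rt)
        frags <- c(frags, target)
        carrier_idx <- length(frags)
      }
      ord <- sample.int(length(frags))
      frags <- frags[ord]
      if (plant) carrier_idx <- which(ord == carrier_idx)
      # random orientation
      flip <- stats::runif(length(frags)) < 0.5
      frags[flip] <- reverse_complement(frags[flip])
      ids <- sprintf("b%d_f%02d", b, seq_along(frags))
      truth[[b]] <- if (plant) ids[[carrier_idx]] else NA_character_
      rows[[b]] <- tibble::tibble(id = ids, taxon = sprintf("batch %d", b),
                                  group = "query", residues = frags,
                                  batch = b)
    }
    seqs <- dplyr::bind_rows(rows)
    validate_sequence_set(seqs)
    # independent re-check: exactly one carrier per planted batch
    for (b in seq_len(n_batches)) {
      hits <- vapply(seqs$residues[seqs$batch == b], contains_sig, logical(1L))
      stopifnot(sum(hits) == (if (plant) 1L else 0L))
    }
    list(sequences = seqs,
         truth = list(carrier_id = truth, planted = plant,
                      signature = signature, seed = seed))
  })
}

#' The packaged demonstration scenario
#'
#' Builds the worked-example dataset of the package: an ingroup whose records
#' share the packaged 55-bp candidate fragment except for one record with
#' substitutions at fragment positions 20 and 44 — immediately outside the
#' 23-bp signature window at positions 21–43 — and a period-23 outgroup
#' (see [generate_outgroup()]). Evaluating the packaged candidate windows
#' against this scenario reproduces the printed verdict pattern (the long
#' candidates lose conservation, the 20-mer loses specificity, only the
#' 23-mer passes both), and [mine_signature()] recovers the 23-bp signature
#' exactly.
#'
#' @param n_ingroup Number of ingroup records (default 12, >= 2).
#' @param flank_len,flank_mut_rate Ingroup flank parameters (see
#'   [generate_ingroup()]).
#' @param seed Integer seed.
#' @return A list with elements `ingroup`, `outgroup` (sequence-set tibbles)
#'   and `truth` (including `expected_signature`).
#' @export
demo_scenario <- function(n_ingroup = 12L, flank_len = 60L,
                            flank_mut_rate = 0.3, seed = 0L) {
  stopifnot(n_ingroup >= 2L)
  core <- ephedra_candidates()$residues[[1L]]  # the 55-bp fragment
  sig <- ephedra_signature()
  sig_at <- as.integer(regexpr(sig, core, fixed = TRUE))
  ig <- generate_ingroup(n_ingroup, core, flank_len = flank_len,
                         flank_mut_rate = flank_mut_rate, seed = seed)
  seqs <- ig$sequences
  # break conservation just outside the signature window in record 1
  break_pos <- c(sig_at - 1L, sig_at + nchar(sig))
  rec1 <- seqs$residues[[1L]]
  core_at <- ig$truth$core_start
  withr::with_seed(seed + 1L, {
    for (p in break_pos) {
      s <- .substitute_base(rec1, core_at + p - 1L)
      rec1 <- s$residues
    }
  })
  seqs$residues[[1L]] <- rec1
  stopifnot(grepl(sig, rec1, fixed = TRUE),
            !grepl(core, rec1, fixed = TRUE))
  og <- generate_outgroup(core, period = nchar(sig), seed = seed + 2L)
  list(ingroup = seqs, outgroup = og$sequences,
       truth = list(planted_core = core, expected_signature = sig,
                    ingroup_truth = ig$truth, outgroup_truth = og$truth,
                    seed = seed))
}
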