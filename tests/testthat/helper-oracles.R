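# Independent brute-force oracles. These deliberately share no code with the
# package internals: matching is done on exploded character vectors with a
# locally defined IUPAC base-set table, and every placement is enumerated.

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

oracle_compat_matrix <- local({
  syms <- names(oracle_iupac_sets)
  m <- matrix(FALSE, 15L, 15L, dimnames = list(syms, syms))
  for (x in syms) for (y in syms) {
    m[x, y] <- length(intersect(oracle_iupac_sets[[x]], oracle_iupac_sets[[y]])) > 0L
  }
  m
})

oracle_chars_match <- function(a, b, policy) {
  if (policy == "strict") return(a == b)
  oracle_compat_matrix[cbind(a, b)]
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
            S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# all substrings of x with length in [min_len, max_len]
oracle_substrings <- function(x, min_len, max_len = nchar(x)) {
  n <- nchar(x)
  out <- character()
  for (L in seq.int(min_len, min(max_len, n))) {
    out <- c(out, substring(x, seq_len(n - L + 1L), seq_len(n - L + 1L) + L - 1L))
  }
  unique(out)
}

oracle_contains <- function(window, subject, policy = "strict") {
  m <- nchar(window)
  n <- nchar(subject)
  if (m > n) return(FALSE)
  wc <- strsplit(window, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  for (o in seq_len(n - m + 1L)) {
    if (all(oracle_chars_match(wc, sc[o:(o + m - 1L)], policy))) return(TRUE)
  }
  FALSE
}

oracle_fraction <- function(window, residues, policy = "strict") {
  mean(vapply(residues, oracle_contains, logical(1L), window = window,
              policy = policy))
}

# exhaustive-enumeration conserved regions: the set of qualifying substrings
# not contained (as a contiguous substring) in another qualifying substring
oracle_conserved_regions <- function(residues, min_len, threshold = 1,
                                     policy = "strict") {
  cands <- unique(unlist(lapply(residues, oracle_substrings, min_len = min_len)))
  qual <- cands[vapply(cands, function(w) {
    oracle_fraction(w, residues, policy) >= threshold
  }, logical(1L))]
  if (length(qual) <= 1L) return(sort(qual))
  keep <- vapply(seq_along(qual), function(i) {
    !any(vapply(seq_along(qual)[-i], function(j) {
      nchar(qual[[j]]) > nchar(qual[[i]]) &&
        oracle_contains(qual[[i]], qual[[j]], "strict")
    }, logical(1L)))
  }, logical(1L))
  sort(qual[keep])
}

# exhaustive minimum distance over every full-length placement on every
# record (and its reverse complement when both_strands)
oracle_min_distance <- function(window, residues, both_strands = TRUE,
                                policy = "compatible", metric = "hamming") {
  wc <- strsplit(window, "")[[1]]
  m <- length(wc)
  best <- Inf
  targets <- residues
  if (both_strands) targets <- c(targets, vapply(residues, oracle_revcomp,
                                                 character(1L)))
  for (s in targets) {
    n <- nchar(s)
    if (metric == "hamming") {
      if (n < m) next
      sc <- strsplit(s, "")[[1]]
      for (o in seq_len(n - m + 1L)) {
        d <- sum(!oracle_chars_match(wc, sc[o:(o + m - 1L)], policy))
        best <- min(best, d)
      }
    } else {
      # infix edit distance: min adist over all substrings (ACGT-only use)
      subs <- unlist(lapply(seq_len(n), function(a) {
        substring(s, a, seq.int(a, n))
      }))
      best <- min(best, min(utils::adist(window, subs)), m)
    }
  }
  best
}

# exhaustive minimal conserved+specific window length (threshold 1)
oracle_mine_length <- function(ingroup, outgroup, min_len, max_len, d_min = 1L) {
  first <- ingroup[[1]]
  for (L in seq.int(min_len, min(max_len, nchar(first)))) {
    wins <- unique(substring(first, seq_len(nchar(first) - L + 1L),
                             seq_len(nchar(first) - L + 1L) + L - 1L))
    for (w in wins) {
      if (all(vapply(ingroup, oracle_contains, logical(1L), window = w,
                     policy = "strict")) &&
          oracle_min_distance(w, outgroup) >= d_min) {
        return(L)
      }
    }
  }
  NA_integer_
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_set <- function(k, len_range, group, prefix = "s") {
  lens <- sample(seq.int(len_range[1], len_range[2]), k, replace = TRUE)
  nucsig::sequence_set(sprintf("%s%02d", prefix, seq_len(k)),
                       vapply(lens, random_dna, character(1L)), group)
}

# a random set sharing a planted common block (for conserved-region cases)
random_set_with_block <- function(k, block_len, flank_max, group = "ingroup") {
  block <- random_dna(block_len)
  res <- vapply(seq_len(k), function(i) {
    paste0(random_dna(sample.int(flank_max + 1L, 1L) - 1L), block,
           random_dna(sample.int(flank_max + 1L, 1L) - 1L))
  }, character(1L))
  nucsig::sequence_set(sprintf("r%02d", seq_len(k)), res, group)
}
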