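test_that("complementary matches are found on the minus strand", {
  og <- sequence_set("o1", "TTTTTTT", "outgroup")
  both <- min_outgroup_distance(og, "AAAA")
  expect_equal(both$min_distance, 0)
  expect_identical(both$nearest_strand, "-")
  plus_only <- min_outgroup_distance(og, "AAAA",
                                     specificity_policy(both_strands = FALSE))
  expect_equal(plus_only$min_distance, 4)
  expect_identical(plus_only$nearest_strand, "+")
})

test_that("exact occurrences give distance zero with correct placement", {
  og <- sequence_set("o1", "GGACGTCC", "outgroup")
  s <- min_outgroup_distance(og, "ACGT")
  expect_equal(s$min_distance, 0)
  expect_identical(s$nearest_offset, 3L)  # 1-based
  expect_identical(s$nearest_strand, "+")
  expect_false(is_specific(og, "ACGT"))
})

test_that("a single-substitution outgroup copy scores distance one", {
  s6 <- ephedra_signature()
  mutated <- s6
  substr(mutated, 12, 12) <- if (substr(s6, 12, 12) == "A") "C" else "A"
  og <- sequence_set("o1", mutated, "outgroup")
  sc <- min_outgroup_distance(og, s6)
  expect_equal(sc$min_distance, 1)
  expect_equal(sc$min_distance, oracle_min_distance(s6, og$residues))
  expect_true(is_specific(og, s6))
  expect_true(is_specific(og, s6, specificity_policy(d_min = 1)))
  expect_false(is_specific(og, s6, specificity_policy(d_min = 2)))
})

test_that("records shorter than the window contribute infinity; empty outgroup warns", {
  og <- sequence_set("tiny", "ACG", "outgroup")
  s <- min_outgroup_distance(og, "ACGTACGT")
  expect_identical(s$min_distance, Inf)
  expect_warning(s0 <- min_outgroup_distance(og[0, ], "ACGT"), "empty outgroup")
  expect_identical(s0$min_distance, Inf)
  expect_warning(expect_true(is_specific(og[0, ], "ACGT")), "empty outgroup")
})

test_that("outgroup ambiguity codes count as matches under the default compatible policy", {
  og <- sequence_set("o1", "GGANGTCC", "outgroup")
  expect_equal(min_outgroup_distance(og, "ACGT")$min_distance, 0)  # N hides a match
  strict <- specificity_policy(match_policy = "strict")
  expect_equal(min_outgroup_distance(og, "ACGT", strict)$min_distance, 1)
})

test_that("hamming distance agrees with exhaustive placement enumeration", {
  set.seed(23)
  for (i in 1:60) {
    w <- random_dna(sample(3:12, 1))
    og <- random_set(sample(1:3, 1), c(4, 40), "outgroup", prefix = "o")
    for (strands in c(TRUE, FALSE)) {
      pol <- specificity_policy(both_strands = strands)
      got <- min_outgroup_distance(og, w, pol)
      expect_equal(got$min_distance,
                   oracle_min_distance(w, og$residues, both_strands = strands),
                   info = sprintf("i=%d strands=%s", i, strands))
    }
  }
})

test_that("edit-metric distance agrees with adist over enumerated substrings", {
  set.seed(29)
  for (i in 1:25) {
    w <- random_dna(sample(4:10, 1))
    og <- random_set(sample(1:2, 1), c(6, 30), "outgroup", prefix = "o")
    pol <- specificity_policy(metric = "edit", match_policy = "strict")
    got <- min_outgroup_distance(og, w, pol)
    expect_equal(got$min_distance,
                 oracle_min_distance(w, og$residues, metric = "edit",
                                     policy = "strict"),
                 info = i)
  }
})

test_that("edit distance never exceeds hamming distance", {
  set.seed(41)
  for (i in 1:20) {
    w <- random_dna(8)
    og <- random_set(2, c(10, 30), "outgroup", prefix = "o")
    h <- min_outgroup_distance(og, w, specificity_policy(match_policy = "strict"))
    e <- min_outgroup_distance(og, w, specificity_policy(metric = "edit",
                                                         match_policy = "strict"))
    expect_lte(e$min_distance, h$min_distance)
  }
})

test_that("specificity is monotone and strand-symmetric", {
  set.seed(37)
  for (i in 1:25) {
    host <- random_dna(40)
    a <- sample(5:20, 1)
    L <- sample(5:12, 1)
    w <- substr(host, a, a + L - 1)
    og <- random_set(2, c(10, 40), "outgroup", prefix = "o")
    d_w <- min_outgroup_distance(og, w)$min_distance
    # extension monotonicity: a superstring is at least as distant
    wider <- substr(host, max(1, a - 2), min(40, a + L + 1))
    expect_gte(min_outgroup_distance(og, wider)$min_distance, d_w)
    # strand symmetry
    expect_equal(min_outgroup_distance(og, reverse_complement(w))$min_distance, d_w)
  }
})

test_that("min distance cross-checks against Biostrings countPattern", {
  set.seed(43)
  for (i in 1:10) {
    w <- random_dna(8)
    og <- random_set(2, c(15, 40), "outgroup", prefix = "o")
    got <- min_outgroup_distance(og, w, specificity_policy(both_strands = FALSE,
                                                           match_policy = "strict"))
    counts <- vapply(0:8, function(k) {
      sum(vapply(og$residues, function(s) {
        Biostrings::countPattern(w, s, max.mismatch = k)
      }, integer(1)))
    }, numeric(1))
    expect_equal(got$min_distance, (0:8)[which(counts > 0)[1]])
  }
})
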