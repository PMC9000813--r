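test_that("evaluate_candidates composes conservation and specificity per window", {
  ig <- sequence_set(c("a", "b"), c("TTACGGA", "CACGGTT"), "ingroup")
  og <- sequence_set("o", "TTTTTTTT", "outgroup")
  ev <- evaluate_candidates(c("ACGG", "ACGGA", "CCCC"), ig, og)
  expect_identical(ev$residues, c("ACGG", "ACGGA", "CCCC"))
  expect_identical(ev$conserved, c(TRUE, FALSE, FALSE))
  expect_true(all(ev$specific[1:2]))
  # a window absent from one of two records is unconserved regardless of outgroup
  expect_false(ev$conserved[[2]])
  # every base present in both sets: 1-mers are conserved but not specific
  ig1 <- sequence_set(c("a", "b"), c("ACGT", "TGCA"), "ingroup")
  og1 <- sequence_set("o", "ACGT", "outgroup")
  ev1 <- evaluate_candidates("A", ig1, og1)
  expect_true(ev1$conserved)
  expect_false(ev1$specific)
})

test_that("the packaged demonstration scenario reproduces the printed verdict pattern", {
  sc <- demo_scenario(seed = 0)
  ev <- evaluate_candidates(ephedra_candidates(), sc$ingroup, sc$outgroup)
  both <- ev$conserved & ev$specific
  expect_identical(sum(both), 1L)
  expect_identical(ev$residues[both], ephedra_signature())
  expect_identical(ev$length[both], 23L)
  # the pattern, not just the winner: long candidates lose conservation,
  # the short one loses specificity
  expect_identical(ev$conserved, c(rep(FALSE, 5), TRUE, TRUE))
  expect_identical(ev$specific, c(rep(TRUE, 6), FALSE))
})

test_that("sweep_lengths enumerates the expected sub-window counts", {
  s1 <- ephedra_candidates()$residues[[1]]
  ig <- sequence_set("a", s1, "ingroup")
  og <- sequence_set("o", random_dna(80), "outgroup")
  expect_identical(nrow(sweep_lengths(s1, ig, og, lengths = 55)), 1L)
  expect_identical(nrow(sweep_lengths(s1, ig, og, lengths = 23)), 33L)
  all_sub <- sweep_lengths(s1, ig, og, min_len = 20)
  expect_identical(nrow(all_sub), sum(56L - 20:55))  # 666
  expect_identical(unique(diff(unique(all_sub$length))) <= 0, TRUE)  # descending
  expect_error(sweep_lengths(s1, ig, og, lengths = 56), "exceeds region length")
  # sub-windows are faithful
  expect_true(all(mapply(function(w, st, L) substr(s1, st, st + L - 1) == w,
                         all_sub$residues, all_sub$start, all_sub$length)))
})

test_that("mine_signature recovers the planted minimal length and satisfies both criteria", {
  core <- ephedra_candidates()$residues[[1]]
  ig <- generate_ingroup(6, core, flank_len = 40, seed = 101)
  og <- generate_outgroup(core, period = 23, seed = 102)
  res <- mine_signature(ig$sequences, og$sequences, min_len = 15, max_len = 55)
  expect_identical(res$signature$length, 23L)
  expect_equal(res$signature$conservation_fraction, 1.0)
  expect_gte(res$signature$min_distance, 1)
  # audit consistency: every shorter evaluated window fails a criterion
  shorter <- res$evaluations[res$evaluations$length < res$signature$length, ]
  expect_true(all(!shorter$conserved | !shorter$specific))
})

test_that("an unrelated random outgroup admits a signature at the minimum length", {
  set.seed(53)
  core <- random_dna(40)
  ig <- generate_ingroup(4, core, flank_len = 30, seed = 9)
  repeat {
    og <- random_set(3, c(40, 60), "outgroup", prefix = "o")
    if (oracle_min_distance(substr(core, 1, 15), og$residues) >= 1) break
  }
  res <- mine_signature(ig$sequences, og, min_len = 15, max_len = 40)
  expect_identical(res$signature$length,
                   oracle_mine_length(ig$sequences$residues, og$residues, 15L, 40L))
})

test_that("no common substring yields an empty result carrying the audit", {
  ig <- sequence_set(c("a", "b"),
                     c(strrep("AC", 20), strrep("GT", 20)), "ingroup")
  og <- sequence_set("o", random_dna(40), "outgroup")
  res <- mine_signature(ig, og, min_len = 15, max_len = 40)
  expect_null(res$signature)
  expect_false(glance(res)$found)
})

test_that("an empty outgroup returns the shortest conserved window with a warning", {
  ig <- generate_ingroup(3, random_dna(40), flank_len = 20, seed = 3)$sequences
  og <- ig[0, ]
  og$group <- character(0)
  expect_warning(res <- mine_signature(ig, og, min_len = 15, max_len = 40),
                 "empty outgroup")
  expect_identical(res$signature$length, 15L)
  expect_identical(res$signature$min_distance, Inf)
})

test_that("mined winner length equals the exhaustive-search minimum on random instances", {
  set.seed(61)
  for (i in 1:25) {
    ig <- random_set_with_block(sample(2:4, 1), block_len = sample(12:25, 1),
                                flank_max = 10)
    og <- random_set(sample(1:3, 1), c(10, 60), "outgroup", prefix = "o")
    res <- mine_signature(ig, og, min_len = 4, max_len = 30)
    expected <- oracle_mine_length(ig$residues, og$residues, 4L, 30L)
    if (is.na(expected)) {
      expect_null(res$signature, info = i)
    } else {
      expect_identical(res$signature$length, expected, info = i)
      expect_equal(conservation_fraction(ig, res$signature$residues), 1.0)
      expect_gte(min_outgroup_distance(og, res$signature$residues)$min_distance, 1)
    }
  }
})

test_that("select_signature applies the shortest-dual-positive rule to a flag table", {
  t3 <- ephedra_candidates()
  sel <- select_signature(t3)
  expect_identical(sel$length, 23L)
  expect_identical(sel$residues, ephedra_signature())
  none <- t3
  none$conserved <- FALSE
  expect_identical(nrow(select_signature(none)), 0L)
})

test_that("tidy, glance and autoplot expose the audit trail", {
  sc <- demo_scenario(seed = 1)
  res <- mine_signature(sc$ingroup, sc$outgroup)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(sum(td$winner), 1L)
  expect_identical(td$residues[td$winner], res$signature$residues)
  gl <- glance(res)
  expect_identical(gl$found, TRUE)
  expect_identical(gl$length, 23L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_sweep(res$evaluations), "ggplot")
})
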