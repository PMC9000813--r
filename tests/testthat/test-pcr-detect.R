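test_that("find_primer_sites locates exact and mismatched sites with a clamped 3' end", {
  mh <- mh_primers()
  tpl <- sequence_set("t1", paste0(random_dna(20), mh$fwd, random_dna(20)), "query")
  sites <- find_primer_sites(tpl, mh$fwd)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$offset, 21L)
  expect_identical(sites$strand, "+")
  expect_identical(sites$mismatches, 0L)

  # strand symmetry: the reverse-complemented template gives a minus-strand site
  tpl_rc <- sequence_set("t1rc", reverse_complement(tpl$residues), "query")
  sites_rc <- find_primer_sites(tpl_rc, mh$fwd)
  expect_identical(nrow(sites_rc), 1L)
  expect_identical(sites_rc$strand, "-")

  # an internal mismatch is tolerated; the same mismatch in the 3'-terminal
  # bases is not
  internal <- mh$fwd
  substr(internal, 5, 5) <- if (substr(internal, 5, 5) == "A") "G" else "A"
  tpl2 <- sequence_set("t2", paste0("GG", internal, "GG"), "query")
  expect_identical(nrow(find_primer_sites(tpl2, mh$fwd, max_mismatch = 1)), 1L)
  tail_mut <- mh$fwd
  n <- nchar(tail_mut)
  substr(tail_mut, n - 1, n - 1) <- if (substr(tail_mut, n - 1, n - 1) == "A") "G" else "A"
  tpl3 <- sequence_set("t3", paste0("GG", tail_mut, "GG"), "query")
  expect_identical(nrow(find_primer_sites(tpl3, mh$fwd, max_mismatch = 1,
                                          three_prime_exact = 3)), 0L)
  expect_identical(nrow(find_primer_sites(tpl3, mh$fwd, max_mismatch = 1,
                                          three_prime_exact = 0)), 1L)
})

test_that("degenerate primer bases match compatible template bases", {
  tpl <- sequence_set("t", "GGGTACGTAGGG", "query")
  hits <- find_primer_sites(tpl, "TRCGT", max_mismatch = 0)           # R ~ A
  expect_identical(nrow(hits[hits$strand == "+", ]), 1L)
  expect_identical(hits$offset[hits$strand == "+"], 4L)
  expect_identical(nrow(find_primer_sites(tpl, "TYCGT", max_mismatch = 0)), 0L)  # Y !~ A
})

test_that("amplify predicts the 150-bp product from the constructed template", {
  mh <- mh_primers()
  tpl <- sequence_set("t1", paste0(mh$fwd, random_dna(113),
                                   reverse_complement(mh$rev)), "query")
  amp <- amplify(tpl, mh)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$length, 19L + 113L + 18L)  # 150
  expect_identical(amp$residues, tpl$residues)
  expect_identical(substr(tpl$residues, amp$start, amp$end), amp$residues)

  # missing reverse site: no product (negative control)
  tpl2 <- sequence_set("t2", paste0(mh$fwd, random_dna(113)), "query")
  expect_identical(nrow(amplify(tpl2, mh)), 0L)
  # product cap
  expect_identical(nrow(amplify(tpl, mh, max_product_len = 100)), 0L)
})

test_that("amplicons from a signature-bearing template contain the signature", {
  mh <- mh_primers()
  sig <- ephedra_signature()
  insert <- paste0(random_dna(40), sig, random_dna(50))
  tpl <- sequence_set("its2", paste0(random_dna(25), mh$fwd, insert,
                                     reverse_complement(mh$rev), random_dna(25)),
                      "query")
  amp <- amplify(tpl, mh)
  expect_identical(nrow(amp), 1L)
  expect_true(grepl(sig, amp$residues, fixed = TRUE))
  expect_identical(amp$length, 19L + nchar(insert) + 18L)
})

test_that("detect_signature reports best placement, strand and mismatches", {
  sig <- ephedra_signature()
  q1 <- sequence_set("q1", sig, "query")
  d1 <- detect_signature(q1, sig)
  expect_identical(d1$found, TRUE)
  expect_identical(d1$position, 1L)
  expect_identical(d1$strand, "+")
  expect_identical(d1$mismatches, 0L)

  host <- random_dna(120)
  q2res <- paste0(substr(host, 1, 40), reverse_complement(sig),
                  substr(host, 41, 120 - nchar(sig) - 40))
  q2 <- sequence_set("q2", q2res, "query")
  d2 <- detect_signature(q2, sig)
  expect_identical(d2$found, TRUE)
  expect_identical(d2$strand, "-")
  expect_identical(d2$position, 41L)

  # not found => NA fields
  q3 <- sequence_set("q3", strrep("AT", 40), "query")
  d3 <- detect_signature(q3, sig)
  expect_identical(d3$found, FALSE)
  expect_true(is.na(d3$position) && is.na(d3$strand) && is.na(d3$mismatches))
})

test_that("detection flags are invariant under query reverse complement, strands flip", {
  set.seed(17)
  sig <- ephedra_signature()
  gen <- generate_mixture_queries(3, sig, n_nontarget = 3, seed = 5)
  q <- gen$sequences
  d_fwd <- detect_signature(q, sig)
  q_rc <- q
  q_rc$residues <- reverse_complement(q_rc$residues)
  d_rc <- detect_signature(q_rc, sig)
  expect_identical(d_fwd$found, d_rc$found)
  flip <- c(`+` = "-", `-` = "+")
  expect_identical(unname(flip[d_fwd$strand[d_fwd$found]]),
                   d_rc$strand[d_rc$found])
})

test_that("zero-mismatch strict detection is exactly substring search", {
  set.seed(19)
  for (i in 1:20) {
    sig <- random_dna(10)
    q <- random_set(4, c(20, 80), "query", prefix = "q")
    d <- detect_signature(q, sig, max_mismatch = 0, policy = "strict")
    naive <- grepl(sig, q$residues, fixed = TRUE) |
      grepl(sig, reverse_complement(q$residues), fixed = TRUE)
    expect_identical(d$found, naive)
  }
})

test_that("ambiguity codes in queries match the signature under the compatible default", {
  sig <- "ACGTACGT"
  q <- sequence_set("q", "GGACGTRCGTGG", "query")  # R covers the A
  expect_true(detect_signature(q, sig)$found)
  expect_false(detect_signature(q, sig, policy = "strict")$found)
  expect_s3_class(plot_detection(detect_signature(q, sig)), "ggplot")
})
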