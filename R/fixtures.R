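# Packaged worked-example fixtures: the published candidate-length sweep for
# the Ephedra ITS2 signature (candidates S1-S7 with their intergeneric
# specificity / intragenus conservation verdicts from a BLAST screen against
# GenBank) and the MH-1F/MH-1R detection primer pair. The verdict flags are
# fixture labels from the original database screen, not locally recomputable
# facts; the package's own scoring reproduces the same pattern on the
# packaged synthetic scenario (see demo_scenario()).

.ephedra_candidates <- tibble::tibble(
  no = paste0("S", 1:7),
  residues = c(
    "TCGGGGGGACGGCCTTGACCGTCCGGTCCGCCTCGGCGGTGCGGTCGGTTGAAAT",
    "GGGGGACGGCCTTGACCGTCCGGTCCGCCTCGGCGGTGCGGTCGG",
    "GCCTTGACCGTCCGGTCCGCCTCGGCGGTGCGGTC",
    "GACCGTCCGGTCCGCCTCGGCGGTGCGGTC",
    "CCGTCCGGTCCGCCTCGGCGGTGCGGT",
    "GTCCGGTCCGCCTCGGCGGTGCG",
    "CCGGTCCGCCTCGGCGGTGC"
  ),
  length = c(55L, 45L, 35L, 30L, 27L, 23L, 20L),
  specific = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
  conserved = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
)

#' Packaged candidate-sweep table (Ephedra ITS2 signature candidates)
#'
#' The seven nested candidate windows S1-S7 of the published length sweep,
#' with their printed lengths and verdicts: `specific` is the intergeneric
#' specificity verdict (at least one variation from every non-Ephedra
#' sequence in the database screen) and `conserved` the intragenus
#' conservation verdict (no variation across the downloaded Ephedra ITS2
#' sequences). S2-S7 are contiguous substrings of the 55-bp fragment S1; the
#' 23-bp candidate S6 is the unique one with both verdicts positive and is
#' the published signature.
#'
#' @return A tibble with columns `no`, `residues`, `length`, `specific`,
#'   `conserved`.
#' @seealso [ephedra_signature()], [mh_primers()], [check_fixtures()]
#' @export
ephedra_candidates <- function() .ephedra_candidates

#' The packaged 23-bp Ephedra genus signature
#'
#' @return The signature string `GTCCGGTCCGCCTCGGCGGTGCG` (candidate S6 of
#'   [ephedra_candidates()]).
#' @export
ephedra_signature <- function() .ephedra_candidates$residues[[6L]]

#' The packaged MH-1F/MH-1R detection primer pair
#'
#' The primer pair designed to amplify a ~150-bp mini-barcode fragment
#' containing the signature from degraded templates.
#'
#' @return A primer-pair tibble (see [primer_pair()]).
#' @export
mh_primers <- function() {
  primer_pair("TCATCGAGTCTTTGAACGC", "ATGCGAAGGTCCCCTTTT", name = "MH-1")
}

#' Check the packaged fixture invariants
#'
#' Verifies the internal consistency of the packaged fixtures: candidate
#' lengths are (55, 45, 35, 30, 27, 23, 20); S2-S7 each occur as a
#' contiguous substring of S1 and S7 occurs within S6; exactly one candidate
#' has both verdicts positive, namely the 23-mer equal to
#' [ephedra_signature()]; and the selection rule (shortest candidate with
#' both flags) applied to the printed flags returns it.
#'
#' @return `TRUE`, invisibly; stops with an informative error on violation.
#' @export
check_fixtures <- function() {
  t3 <- ephedra_candidates()
  stopifnot(
    identical(t3$length, c(55L, 45L, 35L, 30L, 27L, 23L, 20L)),
    identical(t3$length, nchar(t3$residues)),
    all(vapply(t3$residues, grepl, logical(1L), x = t3$residues[[1L]], fixed = TRUE)),
    grepl(t3$residues[[7L]], t3$residues[[6L]], fixed = TRUE),
    sum(t3$specific & t3$conserved) == 1L,
    t3$residues[t3$specific & t3$conserved] == ephedra_signature(),
    nchar(ephedra_signature()) == 23L
  )
  sel <- select_signature(t3)
  stopifnot(nrow(sel) == 1L, sel$residues == ephedra_signature())
  p <- mh_primers()
  stopifnot(p$fwd == "TCATCGAGTCTTTGAACGC", p$rev == "ATGCGAAGGTCCCCTTTT")
  invisible(TRUE)
}
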