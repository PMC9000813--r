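---
title: "Mining genus-diagnostic nucleotide signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genus-diagnostic nucleotide signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucsig)
library(dplyr)
```

## The problem and the model

A *nucleotide signature* is a short sequence window that identifies a taxon:
it must occur **without any variation** in every sequence of the target group
(the *ingroup* — here, typically ITS2 sequences of a target plant genus such
as *Ephedra*), and it must differ by **at least `d_min` variations** from
every same-length window of every non-target sequence (the *outgroup*).
Because such a window is short (20–50 bp), it can still be amplified and
retrieved from manufactured, multi-ingredient preparations in which DNA is
severely degraded — a setting where full-length barcodes fail.

The two criteria pull in opposite directions as the window grows or shrinks:

* **Conservation is anti-monotone in length.** If a window occurs verbatim in
  every ingroup sequence, so does every contiguous sub-window. Longer windows
  can only lose conservation.
* **Hamming specificity is monotone in length.** The minimum mismatch count
  of a window against all placements in the outgroup can only grow when the
  window is extended: any placement of the extension contains a placement of
  the original. Shorter windows can only lose specificity, eventually
  matching some non-target sequence exactly.

The mining problem is therefore well-posed: find the **shortest** window that
still satisfies both criteria. `mine_signature()` solves it exactly:

1. `find_conserved_regions()` enumerates all *maximal* ingroup-conserved
   windows (two-pointer scan per record; valid because conservation is
   anti-monotone). Anti-monotonicity also means every conserved window is a
   sub-window of a maximal region, so restricting the search to regions loses
   nothing.
2. Per anchor position inside each region, the smallest specific length is
   found by **binary search**, justified by the monotonicity of Hamming
   specificity. When the `edit` metric is selected the argument no longer
   applies and a linear scan is used instead.
3. Ties among equal-length winners go to the leftmost anchor of the earliest
   region, making runs reproducible.

The minimality is *global* over all sub-windows of all conserved regions, not
merely over one nested family of centred candidates; this makes "the unique
minimal signature" well-defined. The full evaluation audit is retained in the
result (`tidy()` on a `signature_result`).

## Conservation without alignment

Conservation is defined as **exact substring presence per sequence**, not as
column identity in a multiple alignment. For the statement that matters —
"no variation in the signature region across the ingroup" — the two are
equivalent, and substring presence is unambiguous for unaligned input, so the
toolkit never builds an alignment and gap characters are stripped on ingest.

Two symbol-matching policies govern IUPAC ambiguity codes:

* `strict` (conservation default): a symbol matches only itself. An `N` in a
  database sequence *breaks* conservation — a signature must be literally
  invariant.
* `compatible` (specificity and detection default): symbols match when their
  base sets intersect. An outgroup `N` *could* hide a true match, so it
  counts as one; this is the conservative direction for specificity claims,
  and the right semantics for degenerate primer bases and Sanger consensus
  codes in queries.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 1.0 | required conservation fraction; 1.0 is the standard criterion, lower values tolerate database errors (warned) |
| `d_min` | 1 | required minimum outgroup distance ("at least one variation") |
| `metric` | `hamming` | per-position mismatches over full-length placements; `edit` handles indel-containing outgroups (slower, linear scan) |
| `both_strands` | `TRUE` | outgroup and query orientation is arbitrary |
| `min_len`, `max_len` | 15, 55 | the practical mini-barcode range: published sweeps explore 20–55 bp, and both failure modes (long → unconserved, short → unspecific) sit inside it |
| `max_mismatch` (primers) | 2 | PCR practice tolerates internal mismatches |
| `three_prime_exact` | 3 | polymerase extension requires a matched 3' end |
| `max_mismatch` (detection) | 0 | detection is exact retrieval of the signature |

Coordinates in all result tibbles are 1-based inclusive (`substr`
convention); `position`/`offset` columns are plus-strand positions even for
minus-strand hits.

## The synthetic-data generators

The generators produce data with *planted, independently re-verified* ground
truth, so every pipeline stage is testable without downloads.

`generate_ingroup()` emulates an intragenus sequence set: a shared core
planted between flanks derived from a common ancestor flank and mutated at
0.3 per site — roughly the divergence regime where flanks stop sharing long
windows while the core stays identical. The flank bases immediately adjacent
to the core rotate across records; without that guard a junction base
survives unmutated in every record with appreciable probability and the
conserved block extends past the core by chance.

`generate_outgroup()` plants an exact minimal specific length `p`. The naive
construction — one core copy substituted at every `p`-th position — does
*not* guarantee this: a window shorter than `p` that spans a substitution is
already Hamming-1 from its homologous placement and matches nothing else, so
it would be specific below `p`. Instead the generator plants `p`
phase-shifted substituted copies (copy *j* substituted at core positions
≡ *j* mod *p*). A window of length `L < p` covers at most `L` of the `p`
residue classes, so some copy is unsubstituted throughout it and it occurs
*exactly* (non-specific); a window of length `≥ p` covers all classes and is
substituted in every copy. The guarantee is then re-checked by brute force
after generation — every shorter core window present, at least one `p`-mer
absent on both strands, decoys included — and spacers/decoys are resampled on
a chance collision. Periods below 4 are rejected outright (random decoys
make 1–3-mers unreliably plantable).

`generate_mixture_queries()` emulates detection in compound preparations:
per batch, one fragment embedding the signature (flanks truncated at random
up to the `degrade` fraction — the signature itself never truncated) among
unrelated fragments, all in random orientation. A `plant = FALSE` variant is
the negative control.

What the generators deliberately do **not** model: realistic molecular
evolution (no transition/transversion bias, no rate heterogeneity, no
indels in the ingroup), chromatogram noise, or taxonomic structure within
the ingroup. Passing tests on synthetic data therefore demonstrate the
*algorithmic* contracts — exactness of the search, the monotonicity laws,
recovery of planted truth — not field performance on any particular genus,
which depends on the completeness of the outgroup the user supplies.

## The packaged demonstration scenario

`demo_scenario()` rebuilds, at test scale, the situation of the published
candidate sweep. Its ingroup shares the packaged 55-bp fragment except that
one record carries substitutions at fragment positions 20 and 44 —
immediately outside the signature window at 21–43. Because all five longer
packaged candidates span position 20 or 44 while the 23-mer and the 20-mer
do not, `evaluate_candidates()` reproduces the printed verdict pattern
(long candidates unconserved, the 20-mer unspecific under a period-23
outgroup, exactly one dual-positive). Mining the scenario returns the
23-bp window `GTCCGGTCCGCCTCGGCGGTGCG` itself:

```{r scenario}
sc <- demo_scenario(seed = 0)
evaluate_candidates(ephedra_candidates(), sc$ingroup, sc$outgroup) |>
  select(no, length, conservation_fraction, conserved, min_distance, specific)

mine_signature(sc$ingroup, sc$outgroup)
```

## Numerical and design choices

* **Distance scanning** encodes residues as 4-bit base-set masks; the
  per-offset mismatch profile is accumulated with one vectorised pass per
  window position. Inside the miner, scans stop early once a distance below
  `d_min` is seen (the verdict is already decided); the winner is re-scored
  exhaustively so reported distances are exact.
* **Infix edit distance** is a row-vectorised dynamic program (free start and
  end in the subject; the horizontal pass uses a running-minimum trick). Its
  minus-strand offsets are approximate (indels blur the placement start);
  Hamming offsets are exact.
* **Tie-breaks** everywhere are deterministic and documented: first record in
  set order, then smallest plus-strand offset, then `+` before `-`.
* **Degenerate inputs**: an empty outgroup makes every window vacuously
  specific — the miner warns and returns the shortest conserved window; an
  outgroup record shorter than the window contributes `Inf`; an empty
  conserved-region set yields an empty result that still carries the audit.
* **Problem sizes** used by the test-suite experiments: oracle-equivalence
  suites run a few hundred random instances of up to 5 sequences × 60 bp
  against exhaustive enumeration; planted-period recovery runs periods 5–30
  at 20 seeds each on 55-bp cores (flankless ingroups, so the planted core is
  the only conserved material — with `min_len = 4`, flanked records would
  contain chance-conserved 4-mers that the miner would correctly prefer);
  the demonstration scenario uses 12 ingroup records with 60-bp flanks.

## Known limitations

* Conservation-as-substring makes no allowance for indels inside the window;
  an ingroup sequence with a single insertion in the region counts as not
  containing the signature (this matches the "no variation" reading, but
  users should know it is strict).
* The specificity verdict is only as good as the outgroup provided; the tool
  replaces a database-wide BLAST screen with exact scoring against a local
  set, so an incomplete outgroup can overstate specificity. The packaged
  verdict flags of the published sweep are fixture labels from the original
  database screen, not locally recomputable facts.
* Scoring is exact and desk-scale (hundreds of sequences × kilobases). There
  is no heuristic seeding; genome-scale outgroups are out of scope.
* Species-level resolution below the target genus is explicitly not a goal:
  the signature is diagnostic of the ingroup as a whole.
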