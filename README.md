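# nucsig

Mining and detection of genus-diagnostic nucleotide signatures.

## The problem

Identifying which plant a processed product was made from is hard when the
product is a manufactured multi-herb preparation: DNA is fragmented by
processing, and full-length barcodes (ITS2, *rbcL*, ...) can no longer be
amplified. A **nucleotide signature** sidesteps this: a short window
(20–50 bp) of a barcode region that is

* **conserved** — it occurs *without any variation* in every sequence of the
  target taxon (the ingroup), and
* **specific** — it lies at Hamming distance ≥ *d*<sub>min</sub> (by default,
  at least one variation) from *every* same-length window of every non-target
  sequence (the outgroup), on either strand.

Because conservation can only degrade as a window grows, and specificity can
only degrade as it shrinks, there is a well-defined **shortest window
satisfying both criteria** — the signature. `nucsig` discovers it exactly:

* `find_conserved_regions()` — all maximal ingroup-conserved windows
  (alignment-free, exact substring semantics, IUPAC-aware);
* `min_outgroup_distance()` / `is_specific()` — sliding-window Hamming (or
  infix edit) scoring against the outgroup;
* `mine_signature()` — global minimal search (binary search per anchor over
  the provably monotone specificity criterion), with a full evaluation audit;
* `amplify()` / `detect_signature()` — in-silico PCR with a primer pair and
  exact signature retrieval in mixed, degraded query sequences;
* `generate_ingroup()` / `generate_outgroup()` / `generate_mixture_queries()`
  — seeded synthetic data with planted, independently re-verified ground
  truth.

Sequence sets are plain tibbles (`id`, `taxon`, `group`, `residues`), so
everything composes with dplyr; mining results support `tidy()`, `glance()`
and `autoplot()`. The package ships the published worked example for the
genus *Ephedra*: the candidate sweep table (`ephedra_candidates()`), the
23-bp signature `GTCCGGTCCGCCTCGGCGGTGCG` (`ephedra_signature()`) and the
MH-1F/MH-1R detection primers (`mh_primers()`).

## Worked example

Mine the signature from the packaged demonstration scenario (an ingroup
sharing the 55-bp candidate fragment, with variation planted just outside
the signature window in one record, against a period-23 outgroup):

```r
library(nucsig)
library(dplyr)

sc <- demo_scenario(seed = 0)
mine_signature(sc$ingroup, sc$outgroup)
#> <signature_result>
#>   criteria: conservation >= 1 (strict), distance >= 1 (hamming, both strands)
#>   searched: 2 conserved region(s), 17 window evaluation(s)
#>   signature: GTCCGGTCCGCCTCGGCGGTGCG (23 bp)
#>   location: ig001:81-103  conservation 1.000  min outgroup distance 1
```

The mined 23-mer occurs in all 12 ingroup records (conservation 1.0) and its
closest outgroup window differs at one position (distance 1 ≥ d_min = 1); no
shorter window passes both tests. Detection in seven synthetic
compound-preparation batches, each carrying one signature fragment among
unrelated degraded fragments:

```r
sig <- ephedra_signature()
mix <- generate_mixture_queries(7, sig, n_nontarget = 5, seed = 3)
detect_signature(mix$sequences, sig) |>
  left_join(mix$sequences[, c("id", "batch")], by = c(query_id = "id")) |>
  summarise(detected = any(found), .by = batch)
#> # A tibble: 7 × 2
#>   batch detected
#>   <int> <lgl>
#> 1     1 TRUE
#> ...
#> 7     7 TRUE
```

In-silico PCR with the packaged primers on a constructed template (forward
primer + 113 nt + reverse-complemented reverse primer) predicts the expected
mini-barcode product:

```r
mh <- mh_primers()
tpl <- sequence_set("t1", paste0(mh$fwd, strrep("A", 113),
                                 reverse_complement(mh$rev)), "query")
amplify(tpl, mh) |> select(template_id, start, end, length)
#> # A tibble: 1 × 4
#>   template_id start   end length
#> 1 t1              1   150    150
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/nucsig` (subcommands `mine`, `score`, `pcr`, `detect`, `simulate`,
`fixtures`).

See `vignettes/signature-mining.Rmd` for the model, the matching policies,
the synthetic-data constructions and their guarantees, and known
limitations.

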