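Package: nucsig
Title: Mining and Detection of Genus-Diagnostic Nucleotide Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers minimal-length diagnostic nucleotide signatures: short
    sequence windows that are exactly conserved across an ingroup sequence set
    (for example, ITS2 sequences of a target genus) and at least a chosen
    number of variations away from every window of every outgroup sequence.
    Provides alignment-free conserved-window discovery, sliding-window Hamming
    (or infix edit) specificity scoring against an outgroup, a length-sweep
    miner that returns the shortest window satisfying both criteria, in-silico
    PCR amplicon prediction with a primer pair, and signature detection in
    mixed or degraded query sequences such as consensus reads from processed
    herbal products. A seeded synthetic-data generator plants signatures with
    known ground truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
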