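Package: codonconserve
Title: Detection of Conserved Rare Codon Clusters in Homologous Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for locating clusters of synonymous rare codons in coding
    sequences and testing whether their positions are conserved across
    homolog families. Implements sliding-window percent MinMax codon-rarity
    profiles, per-alignment-column co-occurrence statistics based on a
    conditional binomial model, a dataset-level circular-shift permutation
    null, terminal trimming relative to gap-free alignment boundaries, and a
    Monte Carlo null built from GC3-matched, codon-pair-matched random
    reverse translations that masks alignment positions whose co-occurrence
    is explained by sequence composition rather than codon rarity.
    Downstream association tests (gene ontology enrichment, domain-boundary
    proximity, length-matched controls) and a fully seeded synthetic-data
    generator with planted signals are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
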