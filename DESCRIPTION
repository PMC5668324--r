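Package: barcodeval
Title: Evaluation of DNA Barcode Loci for Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for evaluating candidate DNA barcode loci and their
    combinations for species identification, as practised in plant barcoding
    studies. Computes per-locus alignment characteristics (variable,
    parsimony-informative and conserved sites, indel events, pairwise
    identity), Kimura two-parameter distance matrices with pairwise deletion,
    nearest-neighbour and barcode-gap analyses, distance-based identification
    (Best Match, Best Close Match, All Species Barcodes) with
    leave-one-out identification rates, character-based identification via
    diagnostic nucleotides and conjunctive rule induction, CAPS
    (cleaved amplified polymorphic sequence) assay design from
    species-specific SNPs and restriction-site scanning, neighbour-joining
    and maximum-parsimony trees with consistency/retention indices,
    bootstrap support and species-monophyly tests, and a seeded forward
    simulator of multi-locus barcode datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    BiocGenerics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
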