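Package: mitohopper
Title: Comparative Mitogenomics of Circular Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for comparative analysis of circular
    insect mitochondrial genomes, built around the rice-planthopper mitogenome
    system. Provides readers and writers for GenBank flat files, FASTA and
    tab-separated feature tables with origin-wrapping circular coordinates;
    base composition and AT/GC-skew statistics; codon usage and relative
    synonymous codon usage (RSCU) under the invertebrate mitochondrial code;
    signed circular gene-order encoding with breakpoint-distance and
    rearrangement-block detection; deterministic cloverleaf tRNA folding and
    arm-completeness classification; control-region tandem-repeat (VNTR) and
    homopolymer-run detection; intraspecific haplotype collapsing, minimum
    spanning networks, nucleotide diversity and two-genome divergence/indel
    reports; and seeded generators of synthetic mitogenomes and population
    samples with planted structure for validation.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
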