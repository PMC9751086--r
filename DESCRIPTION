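Package: crisprki
Title: Design and Founder Analysis of CRISPR Knock-In Alleles Made with
    Single-Stranded Oligo Donors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-base CRISPR-Cas9 knock-in projects that use
    single-stranded oligodeoxynucleotide (ssODN) donors and homology-directed
    repair. Covers codon-aware donor design with silent protospacer-adjacent
    motif (PAM) and seed shield mutations for dual overlapping guides,
    four-category classification of on-target sequencing reads from mosaic
    founder animals, de novo single-nucleotide variant subtraction against a
    wild-type control and a known-SNP catalog, a predicted off-target window
    check, and a genome-wide scan for ectopic homology-directed-repair
    signatures whose companion-mutation offsets are derived from the donor
    design. Includes a seeded simulator that generates every input the
    pipeline consumes, so the whole workflow is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    IRanges,
    Rsamtools,
    S4Vectors,
    VariantAnnotation,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
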