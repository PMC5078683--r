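Package: palmsat
Title: Genome-Wide Microsatellite Marker Discovery and Cross-Genus
    Transferability Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines maximal perfect mono- to hexanucleotide microsatellites
    (simple sequence repeats, SSRs) from genome assemblies, designs flanking
    PCR primer pairs under melting-temperature, length, GC and product-size
    constraints, performs mismatch-tolerant electronic PCR to classify marker
    copy number, screens for markers conserved between two genomes, and
    characterizes SSR distribution relative to genes and transposable
    elements. Includes a seed-controlled synthetic genome generator with
    planted repeats and a divergence operator for validating every stage
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
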