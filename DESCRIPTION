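Package: thermotile
Title: Genome-Aware Primer Design and Amplicon Tiling Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Designs target-specific PCR primer pairs against a reference
    genome by scoring full-length, ungapped primer-template pairings
    ("thermoalignments") with nearest-neighbor hybridization thermodynamics,
    including single-base mismatch parameters, at every candidate off-target
    site. Provides variant-aware target-region masking from VCF files,
    exhaustive unique-oligo enumeration with a configurable filter cascade,
    a seed-and-extend off-target scanner, pair-level compatibility filters,
    and a directed-graph shortest-path solver that selects a minimum set of
    overlapping amplicons tiling a large target region, split into two
    multiplex-compatible groups. Includes a deterministic synthetic-genome
    generator for testing repeat-rich designs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
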