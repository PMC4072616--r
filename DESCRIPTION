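Package: mirsnpscan
Title: Free-Energy Screening of Single-Nucleotide Variants in pre-miRNA
    Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Segments pre-miRNA hairpins into terminal loop, mature miRNA
    duplex and extension duplex, exhaustively introduces single-nucleotide
    substitutions, and scores every variant (known or artificial) by the
    free-energy change of its segment: minimum-free-energy folding for
    terminal loops and linker-joined extension arms, and target 3'UTR
    hybridization energy for mature arms.  Candidate causal variants are
    called with a direction filter and a cumulative-contribution knee
    cutoff, and population-level burden variants are identified by
    Monte-Carlo minor-allele-frequency-weighted score resampling.  Includes
    a synthetic hairpin/SNP/target generator so the whole pipeline is
    testable without external databases.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
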