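Package: g4repeats
Title: Quadruplex-Forming Heptameric Tandem Repeats in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide survey of G-rich heptameric tandem repeats capable of
    forming G-quadruplexes (G4) in bacterial genomes. Detects maximal tandem
    arrays of degenerate 7-mer units seeded by exact consensus heptamers on
    both strands, calls G4 capability from intact G-tract runs, scans for
    generic putative quadruplex motifs, annotates repeats relative to ORF
    annotations (intragenic/intergenic, neighbor orientation, distance bins,
    convergent inverted pairs), summarises consensus position frequency
    matrices and unit-count histograms, classifies cross-genome conservation
    of repeat loci from tabular local-alignment hits with control sets and
    one-sample t-tests, and classifies repeat positions on assembled
    transcripts. Includes seeded synthetic-data generators with full ground
    truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
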