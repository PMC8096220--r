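Package: polpause
Title: Nucleotide-Resolution RNA Polymerase Pause Detection from Nascent Transcription Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for calling single-nucleotide RNA polymerase II pausing
    sites from strand-specific nascent-transcription 3'-end occupancy tracks
    (NET-seq and related protocols). Implements a resampling-based pause
    detecting algorithm with an exact multinomial-maximum null, UMI-based
    PCR-duplicate collapsing and reverse-transcription mispriming filtering,
    rule-based genomic classification of pauses (promoter-proximal, gene-body,
    antisense, intergenic), DNA-sequence feature construction (nucleotide
    skews and identities, RNA-DNA hybrid thermodynamics, nascent-RNA folding
    energy, DNA shape, motif scans, methylation), and a random-forest model of
    pausing determinants with permutation feature importance. A synthetic-data
    generator produces genomes, annotations, occupancy tracks with planted
    pauses and artifact-bearing reads so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    ranger,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
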