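Package: paleohex
Title: Sub-Genome Reconstruction and Polyploidy Dating for Paleohexaploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for paleopolyploid (notably
    paleohexaploid) plant genomes analysed against a diploid reference.
    Detects syntenic gene pairs supported by flanking-gene homology and
    chains them into syntenic fragments; derives genomic blocks from
    breakpoints shared across sub-genome copies; deduces the diploid
    ancestral karyotype from block associations; partitions the
    triplicated genome into least- and more-fractionated sub-genomes
    (LF/MF1/MF2) by retention density; computes codon-level Ks/Ka with
    the Nei-Gojobori (1986) method and dates whole-genome triplication
    from Ks-distribution peaks; tests homoeolog expression dominance
    with exact binomial tests and profiles transposable-element density
    around genes and promoters; classifies duplication modes and runs
    GO over-retention enrichment. Includes a synthetic paleohexaploid
    genome generator with known truth so the entire pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
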