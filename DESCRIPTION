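Package: ofrbarcode
Title: Species Discrimination from DNA Barcodes Using Oligonucleotide
    Frequency Ranges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free species discrimination for DNA-barcode loci
    (COI, matK, rbcL, ITS) based on per-species oligonucleotide frequency
    ranges (OFR): for every di- or trinucleotide the minimum and maximum
    frequency across the accessions of a species is computed, and a species
    pair is resolved when at least one oligonucleotide range is separated by
    a length-derived threshold. Includes the standard comparator criteria
    (uncorrected p-distance and Euclidean distance barcoding-gap tests,
    simple pure/private diagnostic characters), an indel-driven Type I/II
    error analysis for the threshold, a mini-barcode trimming scan, a
    seeded synthetic barcode-dataset generator, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    XVector,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
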