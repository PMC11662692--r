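Package: drsage
Title: Long-Read Transcriptome Analytics for Aging Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analytics for nanopore direct RNA sequencing (DRS)
    over an adult aging time course: derivation of stringent intron and
    intergenic interval sets from a genome annotation, full-length read
    filtering against transcription start sites and poly(A) QC, splice
    junction fidelity statistics, isoform novelty / novel 3'UTR / fusion
    candidate classification, poly(A) tail length analytics with
    abundance-quartile binning and delta-median classes, and
    replicate-consensus inosine (A-to-I) and pseudouridine site calling
    with recoding-consequence annotation. Ships a seeded synthetic-data
    generator that emulates every input format with a machine-readable
    truth manifest, so each stage can be verified exactly at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
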