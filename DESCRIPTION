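Package: baculoprom
Title: Promoter Landscape Analysis for Baculovirus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the late-gene promoter landscape of
    baculovirus genomes such as AcMNPV. Reads annotated circular genomes
    from GenBank flat files, assigns open reading frames to transcript
    abundance classes from RPKM thresholds, extracts 5'UTRs and
    promoter-associated windows under explicit strand-aware coordinate
    conventions, performs exact and Hamming-distance-tolerant octamer and
    motif scanning with genome-wide background calibration, computes 5'UTR
    length and A+T-content statistics by class, measures signed distances
    between homologous repeat (hr) regions and ORF start codons on a
    circular chromosome, and derives anchored per-class IUPAC consensus
    sequences around translation and transcription start sites. A
    synthetic-data generator with a ground-truth manifest makes every
    pipeline stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
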