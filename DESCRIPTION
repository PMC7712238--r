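Package: nemaGATA
Title: Structural Annotation and Classification of Nematode GATA
    Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies GATA-type C4 zinc-finger transcription factors in
    nematode genomes and classifies them into the five structural classes
    (ELT-1, ELT-2, ELT-3, ELT-5, ELT-X). Detects canonical and degenerate
    C4 zinc fingers, basic domains, diagnostic hexapeptides and
    poly-serine segments; maps coding introns into protein codon
    coordinates relative to zinc-finger cysteine landmarks; builds
    landmark-anchored 55-column alignments of DNA-binding domains with
    consensus and conservation statistics; measures paralog proximity and
    orientation; and scans gene flanks for HGATAR sites, inverted
    double-GATA arrangements and polypyrimidine tracts. A seeded
    synthetic-genome generator with a truth manifest supports end-to-end
    recovery scoring of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
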