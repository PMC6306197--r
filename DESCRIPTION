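Package: rdnaintrons
Title: Cataloguing Introns and Auditing Metabarcode Regions in Diatom rDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects insertions in 18S/28S rDNA multiple alignments relative to an
    intron-free reference row, maps them to reference core coordinates by their
    flanking-nucleotide pairs, classifies them as spliceosomal introns (5' GTDHNN
    donor, YTRAC branch site, CT-rich tract, 3' YNHAG acceptor; YTAMAG variant in
    the 28S) or group IC1 intron candidates, and audits the 18S V4/V9 metabarcode
    regions: IUPAC-aware primer matching with critical 3'-end mismatch flagging,
    intron disruption of primer targets, terminal-taxon delineation and
    marker-region discriminability. Includes a neighbor-joining tree builder with
    a deterministic tie-break, conserved-block extraction for group I introns, and
    a synthetic rDNA generator (Jukes-Cantor cores evolved on a known tree with
    grammar-true implanted introns and a machine-readable truth table) so every
    stage is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
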