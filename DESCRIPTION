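Package: circkit
Title: Detection, Quantification and Annotation of Circular RNAs from
    Back-Splice Junction Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A consolidated pipeline for circular RNA (circRNA) analysis from
    chimeric-alignment evidence. Reads STAR-style chimeric junction and linear
    splice-junction tables as well as find_circ- and CIRCexplorer-style caller
    outputs, calls back-splice junctions with splice-motif and annotation
    checks, harmonizes multi-source candidates, applies an artifact filter
    cascade (genomic span, splice-site motif, multi-gene spanning, distinct
    read support with coordinate-based PCR-duplicate flagging), recounts
    back-splice support, and computes abundance metrics (RPM, circular-to-linear
    ratio, percent circularized, host-gene TPM excluding circle-internal
    exons). Annotates parental transcripts, internal exons, genomic origin
    classes, exon-rank spectra and alternative back-splicing, analyzes
    flanking introns for inverted repeat pairs and reverse-complementary
    sequence, and builds metaprofiles of crosslink signal around back-splice
    sites. Includes a deterministic simulator that generates synthetic
    genomes, annotations and junction evidence with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
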