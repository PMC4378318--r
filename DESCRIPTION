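Package: redseqr
Title: Restriction Enzyme Accessibility Profiling (RED-seq) Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide chromatin accessibility profiling with restriction
    endonuclease digestion coupled to deep sequencing (RED-seq). Provides
    degenerate-motif restriction-site indexing, inline-barcode read
    demultiplexing with cleavage-signature quality control, assignment of
    aligned read 5' ends to unique restriction sites, reads-per-million
    normalization, binned metaprofiles and windowed accessibility scores
    around genomic features, per-site differential cut analysis with
    Fisher's exact test, and a ground-truth chromatin digestion simulator
    (nucleosome arrays, nucleosome-free regions, variant nucleosomes,
    sonication and size selection) so every pipeline stage can be validated
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
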