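Package: regionspot
Title: Annotation and Region-Level Scoring of Extratranscriptic DNA Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates DNA variants located outside protein-coding
    transcripts ("extratranscriptic" variants) with regulatory feature
    tracks (promoters, enhancers, CTCF sites, transcription factor
    binding sites, open chromatin, histone marks, conservation), derives
    per-feature weights from positive and negative training variants via
    relative-risk ratios, and computes an additive region score with a
    dichotomous functional/non-functional classification and a two-level
    evidence strength.  Variants can be filtered by candidate genes and
    their promoter windows, by distal regulatory elements linked through
    chromatin-interaction data, by population carrier counts, and by
    phenotype-associated genes.  A deterministic synthetic-fixture
    generator produces every input format the pipeline consumes, with
    planted feature enrichment, so the whole method is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
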