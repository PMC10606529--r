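Package: l1xpress
Title: Locus-Specific Quantification of Young LINE-1 Expression from
    Long-Read RNA-Seq
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies expression of full-length, young
    LINE-1 (L1) retrotransposons from long-read RNA sequencing data.
    Implements candidate-read selection by read length and RepeatMasker
    divergence, pruning of L1Base2 category references (active, inactive,
    intact-only-in-ORF2) against overlapping elements and annotated exons,
    artifact-based locus filtering (read containment, minimum read
    support, read-start consistency, 5' start proximity), split-aware
    bedGraph coverage, and length-weighted normalized expression per L1
    category, together with a fully synthetic ground-truthed data
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    ShortRead,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
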