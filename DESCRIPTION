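Package: varscreen
Title: Variant Prioritization for Forward Genetic Screen Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate causal genes from
    whole-genome resequencing of mutagenized lines in a forward genetic
    screen. Applies GATK-style hard filters to per-line variant calls
    (QD, MQ, QUAL, MQRankSum, SOR, FS, ReadPosRankSum), annotates variants
    into gene-based region classes and codon-level coding consequences,
    removes background mutations shared by every line, excludes variants
    recurring across lines, and ranks surviving genes by loss-of-function
    severity. Includes a synthetic mutagenized-cohort generator (EMS/UV
    mutation spectra, planted causal loss-of-function variants, truth
    tables) so every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
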