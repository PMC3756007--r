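Package: pnpscan
Title: Selection Scans on Pooled Population Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for detecting candidate genes under selection from
    pooled population transcriptome assemblies. Predicts open reading frames
    on frame-annotated transcript contigs, applies conservative post-call SNP
    filters (quality, occurrence, coverage, no indels), classifies retained
    variants as synonymous or nonsynonymous, computes per-gene pN/pS between
    population pairs with Nei-Gojobori (1986) site counting and pathway
    averaging, runs McDonald-Kreitman tests with a neutrality index against
    an outgroup species, and tests GO-term overrepresentation with FDR
    control. Includes a deterministic synthetic-data generator that plants
    fixed differences, polymorphisms and outgroup divergence at known rates
    so every stage can be validated against recorded truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
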