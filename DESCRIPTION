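Package: imprintcall
Title: Detection of Genomic Imprinting from Reciprocal-Cross Seed RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide detection of parent-of-origin allelic expression
    (imprinting) from reciprocal-cross seed RNA-seq. Classifies aligned reads
    as Col or Ler by SNP overlap, builds per-gene allelic count tables for
    both reciprocal crosses, and tests each gene with an exact unconditional
    two-binomial (Storer-Kim-type) test against the tissue-specific null
    (maternal fraction 1/2 in embryo, 2/3 in triploid endosperm). Confident
    fold-change factors built from 95% confidence-interval bounds quantify
    imprinting, strain cis effects, and differential expression; a seed-coat
    contamination filter, coverage filter, upper-quartile Fisher differential
    expression, DMR association, and imprinted-gene mini-cluster detection
    complete the pipeline. A seeded synthetic-data generator with known
    imprinting, cis, and contamination structure supports calibration and
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
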