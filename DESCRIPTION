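Package: sRNAmethyl
Title: Small RNA Classification, Beta-Elimination Enrichment, and
    Target-Site Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 3'-terminal 2'-O-methylation of small
    RNAs in C. elegans style small RNA sequencing libraries. Simulates
    collapsed small RNA libraries (piRNAs, 22G and 26G siRNAs, miRNAs)
    from a synthetic reference with class-specific lengths, 5'
    nucleotides, methylation status, and 3' trimming/tailing; models
    periodate beta-elimination as copy dropout of unmethylated species;
    maps reads by exact matching and classifies them by length, 5'
    nucleotide, and annotated locus; computes reads-per-million
    abundances, log2 enrichment ratios, depletion percentages, and
    2^-ddCt fold changes; decomposes read 3' ends into templated prefix,
    trim, and untemplated tail; and scores guide-target complementarity
    with Watson-Crick, G:U wobble, mismatch, and bulge states under the
    positional rules of a single-site siRNA sensor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
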