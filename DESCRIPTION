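Package: genoprof
Title: Tile-Based RNA-Seq Normalisation, Expression-Profile Colour
    Encoding and Bacterial Genome Annotation Support
Version: 0.1.0
Authors@R:
    person("genoprof", "maintainers", email = "genoprof@example.org",
           role = c("aut", "cre"))
Description: Gene-free, groupwise normalisation of stranded RNA-seq
    depth over fixed-width genome tiles by iterative trimmed scaling;
    HSL colour encoding of multi-timepoint expression profiles rendered
    as Artemis-readable misc_feature annotations and whole-genome
    overview images; a multi-evidence bacterial start-codon scoring and
    selection engine (ribosome-binding-site weight matrix, translational
    coupling, codon-type weights); an iterative suspicion-score ORF
    filter with reciprocal-best-hit orthology support; and a
    pileup-based caller of unambiguous substitution and single-base
    indel differences for hybrid genome error correction. Includes a
    deterministic synthetic-data generator for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods,
    jsonlite,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
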