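Package: symcomp
Title: Comparative Genomics of Eroding Co-Obligate Symbiont Consortia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for comparative analysis of eroding endosymbiont genomes in
    multi-partner (di-symbiotic) insect systems. Reads annotated bacterial
    genomes (GenBank flat file or GFF3 plus FASTA), screens coding sequences
    against a reference protein panel by Smith-Waterman local alignment,
    classifies each panel gene as intact, pseudogenized, or missing by an
    ortholog length-ratio rule (pseudogene when the longest coding fragment is
    shorter than 80 percent of its reference ortholog), evaluates
    biosynthetic-pathway completeness per genome and for the symbiont
    consortium with alternative-enzyme logic, screens virulence-factor
    repertoires at identity and coverage thresholds (flagellum completeness
    classes, siderophore locus completeness), and computes genome-erosion and
    prevalence summary statistics. A seeded synthetic genome-degradation
    generator with known ground truth makes every stage testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
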