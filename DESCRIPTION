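Package: phagemap
Title: Genome-Wide CRISPRi Essentiality Mapping and Barcoding Toolkit for Phages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design tools and analysis methods for systematic gene
    essentiality mapping in bacteriophages by arrayed Cas12a CRISPRi.
    Scans annotated phage genomes for TTTV PAM sites and emits one crRNA
    spacer per gene within a positional window of the coding sequence,
    generates Golden-Gate-compatible cloning oligos, computes efficiency
    of plating (EOP) from spot-titration plaque counts with censoring and
    essential/nonessential classification, interprets calls in light of
    CRISPRi roadblock polarity over transcriptional units (including
    trans-complementation re-evaluation), and designs DNA-barcode
    insertion constructs with Barseq-style barcode quantification from
    sequencing reads. Includes seeded simulators for phage-like genomes,
    Poisson plaque counts, and barcode amplicon reads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
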