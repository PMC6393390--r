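Package: dehydrin
Title: Dehydrin Motif Detection, F-Segment Mining, and Seasonal Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the sequence analysis of plant dehydrins (group-2 LEA
    proteins): fuzzy detection of the conserved Y-, S-, K-, F- and
    histidine-rich segments, classification of proteins into the YSK
    structural nomenclature (YnSKn, SKn, YnKn, Kn, KnS) including
    multi-copy F-segment (FnSKn) architectures, Smith-Waterman mining of
    expanded F-segments from protein databases with duplicate and
    gapped-segment filtering, positional consensus and information-content
    profiling of mined segments with neighbor-joining clustering,
    charge/hydropathy/pI/molecular-weight profiling of conserved segments,
    and relative quantification of seasonal qPCR expression data by the
    comparative Ct (2^-ddCt) method. Synthetic-data generators with known
    ground truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    withr
Config/testthat/edition: 3
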