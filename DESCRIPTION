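Package: crypticsplice
Title: Discovery and Re-Splicing Analysis of EJC-Suppressed Cryptic Splice Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting cryptic splice junctions that are
    de-repressed when the exon junction complex (EJC) is depleted.
    Quantifies split reads from spliced alignments with strict overhang
    and mismatch filters, normalizes to library depth, computes a local
    percent-selected-index (PSI), and applies a count and PSI fold-change
    cascade across knockdown conditions to call cryptic junctions. Cryptic
    splice sites are classified against the annotation (exonic/intronic
    5'/3' and novel alternative), positioned on mature mRNA relative to
    exon-exon junctions, and scored with position weight matrices trained
    from annotated splice sites. A one-occurrence-per-sequence EM motif
    finder derives a branchpoint model from intronic sequence. A scanner
    detects splice sites regenerated at exon-exon junctions after intron
    removal and predicts mRNA re-splicing events together with their
    reading-frame consequences. Includes a synthetic spliced-read
    simulator with a truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
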