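Package: pasedit
Title: Genome-Wide Discovery of Base-Editable Polyadenylation Signals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Finds polyadenylation signal (PAS) hexamers that an adenine base
    editor can disrupt. Combines PAS motif occurrences (AATAAA, ATTAAA) with
    Cas9 PAM placement so that a disruptable adenine falls inside the editor's
    activity window, on either strand, via two interchangeable scan engines (a
    regular-expression construction and a direct positional enumeration).
    Reads GENCODE polyA GFF3 annotations, intersects them with scan results to
    summarise how many annotated signals are editable, enumerates near-match
    off-target loci for a guide with a three-criterion candidate filter, and
    ships a deterministic synthetic-genome fixture generator with brute-force
    oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: CRISPR, MotifDiscovery, SequenceMatching, GenomeAnnotation
RoxygenNote: 7.3.3
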