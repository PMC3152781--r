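Package: trscan
Title: Exact Detection and Analysis of Perfect and Imperfect Tandem Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An exact, alignment-score driven scanner for perfect and
    imperfect tandem repeats in nucleotide sequences, together with the
    downstream statistics needed for genome-scale repeat surveys.  The
    detector finds all repeats in a configurable unit-size range whose
    alignment against a perfect repeat counterpart reaches a minimum score
    (match +1, mismatch -5, gap -5, N 0, first unit unscored), with
    bounded imperfection bridging and an X-drop style maximum score
    reduction.  Companion modules canonicalize repeat units into repeat
    types and motifs under rotation and reverse complement, compute
    N-corrected density, length and perfection tables, stratify repeats by
    genomic region (CDS, intron, UTRs, intergenic) from GFF annotations
    with sense-strand extraction, and generate seeded synthetic genomes
    with planted repeats of known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
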