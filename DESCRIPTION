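Package: umihla
Title: UMI-Based Long-Read Amplicon Consensus, HLA Typing and
    Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for unique molecular identifier (UMI) tagged long-read
    amplicon sequencing of HLA transcripts. Orients and trims reads against
    locus-specific primer pairs, extracts dual-end UMIs, clusters them with
    an error-tolerant directional rule, builds per-molecule consensus
    sequences by alignment pileup majority vote, assigns consensus reads to
    alleles of an IMGT-style cDNA reference, calls per-locus genotypes with
    allele-balance flags, and normalizes per-allele UMI counts to log2
    counts-per-million. A read simulator with complete ground truth
    (molecule identity, UMI, allele of origin, applied errors) emulates the
    assay for validation at nanopore-like error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
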