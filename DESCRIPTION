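Package: sexscreen
Title: Sex-Specific Sequence Screening and Marker Genotyping for ZW/XY Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and in-silico validation of sex-specific genomic
    sequences in diploid species whose ZW or XY sex-determination system is
    unknown. Implements a Hardy-Weinberg sampling-design model for the
    autosomal pseudo-marker error rates P_E and P_E-Pool with Monte-Carlo
    simulation and closed-form oracles; a coverage-subtraction screening
    pipeline (same-sex common regions, strict zero-coverage subtraction
    against opposite-sex and single-sex pool libraries, composition filters,
    ZW/XY system inference); read quality control, k-mer genome-size
    estimation and an exact-seed ungapped read mapper; in-silico PCR with
    gel band-pattern prediction and genetic-sex calling; and a synthetic
    diploid genome/cohort generator with ground truth so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
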