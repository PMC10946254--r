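Package: pamscreen
Title: PAM-Anchored Target Screening for CRISPR-Cas12a Species Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide enumeration of PAM-anchored candidate targets for
    CRISPR-Cas12a based species identification, mismatch-tolerant screening of
    those targets against comparator genomes under a Hamming-distance model,
    crRNA spacer derivation, and a qualitative in-silico model of Cas12a
    activation. Includes a seeded synthetic-genome generator (planted targets,
    decoys at fixed mismatch distances, related-genome pairs at a controllable
    identity) so the whole pipeline is testable without downloads, and a
    command-line interface wiring the steps into a single workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
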