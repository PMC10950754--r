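Package: m6adiff
Title: Differential m6A Methylome Analysis for Paired Nanopore Direct-RNA Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Site-level N6-methyladenosine (m6A) stoichiometry from per-site
    modified/total read counts produced by nanopore direct-RNA modification
    callers, a consistency-filtered paired differential-site caller for
    pre/post-treatment designs, interval-based annotation of sites to genes
    and functional regions, RRACH motif characterization, integration with
    gene expression changes to nominate concordantly down-regulated genes,
    and poly(A) tail-length comparison as an mRNA-stability proxy. Includes
    a deterministic synthetic-data generator with planted ground truth so
    every stage of the pipeline can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
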