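Package: circomine
Title: Mining and Comparative Analysis of Endogenous Circoviral Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens genome assemblies for endogenous circoviral elements
    (CVe) with a seeded six-frame translated similarity search, classifies
    loci against a circovirus reference library, reconstructs ancestral
    reading frames with a frameshift-aware protein-to-DNA alignment, calls
    orthologous insertions from genomic flanks, counts germline
    incorporation events under conservative conventions, calibrates
    insertion ages on a host timetree, assigns systematic locus
    identifiers, and characterises within-lineage copy-number expansions
    and their association with flanking retroelements. A synthetic-data
    module plants decayed, duplicated viral insertions into simulated host
    assemblies with full ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    phangorn,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
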