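Package: lineageloss
Title: Detection of Lineage-Specific Gene Loss and Unitary Pseudogenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline that, starting from a single query
    protein, detects lineage-specific losses of a well-established ancestral
    gene across a set of species, rescues intact but un-annotated genes by
    re-annotation, identifies unitary pseudogenes, characterises their
    disabling mutations (nonsense codons, frameshifting indels, splice-site
    edits, exon losses) branch-by-branch against parsimony-reconstructed
    ancestral sequences, and summarises all events on an ultrametric species
    tree via Dollo-like and Sankoff parsimony.  Includes a seeded simulator of
    gene families with planted losses and pseudogenizations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
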