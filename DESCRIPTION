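Package: FeADHtools
Title: Subfamily Classification and Diagnostic-Residue Annotation of
    Iron-Containing Alcohol Dehydrogenases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the iron-containing (type-III) alcohol
    dehydrogenase (FeADH) protein family: a machine-readable registry of the
    19 CDD-defined FeADH subfamilies with their phyletic distribution,
    global pairwise alignment and mapping of query sequences onto human
    ADHFE1 reference numbering, rule-based functional annotation from
    diagnostic residues (coenzyme-specificity position 81, the GGGS
    pyrophosphate-binding motif, the Asp242/His246/His330/His357 metal
    tetrad, HOT-subfamily insertions), seed-profile subfamily classification
    with reciprocal-best-hit confirmation, neighbor-joining phylogenetics
    with bootstrap monophyly support, per-column sequence-logo information
    content, and a synthetic sequence generator that emulates the family's
    divergence structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
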