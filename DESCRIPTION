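Package: primerscreen
Title: In Silico Validation of Degenerate Mini-Barcode PCR Primers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating group-specific degenerate PCR primers
    against multiple-sequence alignments, as used when designing COI
    mini-barcode markers for eDNA metabarcoding.  Provides IUPAC
    ambiguity-code matching, sliding-window conservation (similarity index
    1/D) profiling of an alignment consensus, mismatch-rule primer binding
    analysis with 3'-end constraints, position- and type-weighted mismatch
    penalty scoring with threshold classification, logistic mixed-model
    comparison of primer sets with a species random intercept, Kimura
    two-parameter barcoding-gap analysis, and a seeded synthetic-alignment
    generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
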