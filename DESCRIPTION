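Package: binderID
Title: Identification of Proteinaceous Binders in Artwork Micro-Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-search pipeline for bottom-up proteomic analysis of
    paint micro-samples. Starting from peptide-spectrum-match evidence
    tables (MaxQuant-style TSV) and annotated protein sequence databases,
    the package filters evidence, decides which proteins are confidently
    identified using the two-unique-non-overlapping-peptides rule,
    assesses species-diagnostic peptides under mass-ambiguity rules
    (isoleucine/leucine, deamidation-driven N/D and Q/E, serine/alanine
    near oxidation), applies historical-plausibility filtering and
    parsimony assignment, attributes protein sources (egg yolk, egg
    white, animal glue, hide glue, wool), and estimates percent
    deamidation of asparagine and glutamine with bootstrap uncertainty.
    A seeded synthetic-fixture generator produces species-divergent
    mini-proteomes and evidence tables with known ground truth so the
    whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
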