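Package: regsig
Title: Regulatory Signal Detection and Annotation for Bacterial Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying transcription control signals in annotated
    bacterial genomes: builds position weight matrix profiles from binding-site
    alignments, calibrates trusted/noise/gathering score cutoffs, scans genome
    sequences on both strands with exact score-distribution p-values, filters
    hits by genomic context (orientation, converging regions, intragenic
    placement), detects intrinsic rho-independent terminators, writes results
    into GenBank annotations, infers regulator-anchored transcription units,
    and iteratively optimises profiles across related genomes. Includes a
    synthetic-genome simulator with planted sites, operons and terminators for
    fully self-contained validation, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
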