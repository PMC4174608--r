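Package: ssfilter
Title: Post-Assembly Triage of Strand-Specific De Novo Transcriptomes
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Filters and reduces redundant de novo transcriptome assemblies
    built from dUTP strand-specific RNA-seq libraries. Computes the
    strand-specific log ratio (SSLR) from read-pair orientation, detects and
    removes antisense "leakage" duplicates, applies read-pair support and
    coverage-dip filters, reconciles six-frame open reading frames with
    externally predicted ones, and selects one representative transcript per
    assembler component by a weighted evidence score. Also provides
    mode-centered two-pool differential expression ratios, a pileup-based
    substitution-site scan, best-e-value lowest-common-ancestor taxonomy
    assignment, and a seeded simulator of strand-specific assemblies,
    alignments and homology tables for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
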