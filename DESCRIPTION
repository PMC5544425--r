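Package: sgisplice
Title: Synthetic Genetic Interaction Scoring and Junction-Level Differential Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for scoring synthetic genetic interactions from competitive
    fitness assays under a multiplicative null model (relative fitness,
    expected double-mutant fitness, the synthetic effect epsilon, and a
    three-criterion significance procedure), and for junction-level
    differential alternative-splicing analysis from STAR splice-junction
    count files (alternative junction pairing, relative junction usage,
    Fisher exact testing with Bonferroni control, event-type classification,
    and K-means usage clustering). Includes flanking-region 7-mer motif
    enrichment for RNA-binding-protein cis-elements, expression heatmap
    transforms and set-overlap statistics, and seeded synthetic-data
    generators for competition plates, junction count files, toy genomes
    and motif-planted sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
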