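Package: bhlhscan
Title: Genome-Survey Toolkit for Basic Helix-Loop-Helix Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies basic helix-loop-helix (bHLH) domains in protein
    sequences by best-placement matching of the degenerate consensus motif
    of the family (19 diagnostic sites, two variable-length spacers, a
    nine-mismatch acceptance budget), segments hits into the basic, helix 1,
    loop and helix 2 regions and diagnoses E-box binding capability.
    Classifies accepted domains into the 45 recognised bHLH families and
    supergroups A-F via anchored alignment distance to representative
    domains, with neighbor-joining placement and column-resampled bootstrap
    support. Provides hypergeometric term and pathway enrichment with
    Benjamini-Hochberg correction and per-group coherence, confidence-
    filtered protein-interaction-network construction with degree-based hub
    calling and family-module extraction, fully seeded synthetic-data
    generators with ground-truth tables, and packaged machine-readable
    transcriptions of the Xenopus tropicalis bHLH catalog and enrichment
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
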