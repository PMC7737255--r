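Package: fireladder
Title: Fire Ladder Pattern Detection Across Biomedical Terminologies
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects the three-terminology "fire ladder" topological pattern
    in UMLS-style terminology releases to propose candidate concepts for
    import into a target terminology. Reads MRCONSO/MRREL RRF files, builds
    per-terminology IS-A hierarchies (with self-loop and depth-bounded cycle
    removal), enumerates ordered terminology triples, detects fire ladder
    patterns with an independent brute-force oracle, derives the two
    candidate data sets and per-triple summaries, computes two-rater
    agreement statistics (Cohen's kappa, Krippendorff's alpha), and
    generates synthetic RRF fixtures with planted patterns, near-miss
    decoys, and cycles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
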