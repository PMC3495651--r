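Package: coexvote
Title: Vote-Counting Gene Co-Expression Maps and Guilt-by-Association
    Candidate Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds corpus-level gene co-expression maps from collections of
    multi-condition expression datasets using a vote-counting scheme: within
    each dataset every pair of conditions is compared, genes changing at
    least two-fold are called differentially expressed, and joint
    same-direction calls are tallied across the whole corpus. Per-gene
    "friend" lists (the top fraction of co-expressed partners) feed a
    binomial right-tail guilt-by-association test that ranks every gene
    against a user-supplied seed list, with optional restriction to
    transcription factors and a randomization-based calibration of the
    significance cutoff. Includes a planted-module synthetic corpus
    generator so the full pipeline is testable without external data, plus
    dataset-level quality control (conditional log2 transform, value-range
    filters, annotation-coverage filter, replicate averaging) and
    threshold-network export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
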