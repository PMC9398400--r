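Package: orthotale
Title: Design of Genome-Orthogonal TALE Effector Binding Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing synthetic TALE (transcription
    activator-like effector) binding elements (EBEs) that are orthogonal
    to a host genome. Generates candidate 19-mers under the T0 constraint,
    scans a genome for near-match off-target sites on both strands with a
    pigeonhole seed filter, scores each site with a position-weighted
    RVD-base mismatch score, ranks candidates by the neverword score and
    score-distribution ratio, translates the selected element into a TALE
    repeat (RVD) array, and annotates off-target sites by their position
    relative to gene models. Includes a synthetic-fixture generator with
    planted ground-truth sites so the whole pipeline is testable without
    any genome download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
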