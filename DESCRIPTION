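Package: sigscreen
Title: Automated Marker Gene Signature Screening for Labeled Bulk Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene signatures specific to a target group in labeled
    bulk expression data. Performs pairwise differential expression of the
    target group against every other group (edgeR filtering and TMM
    normalization with limma voom/trend moderated threshold tests),
    aggregates the per-comparison statistics into a rank-product score with a
    bootstrap permutation null, optionally constrains the selection to a
    curated marker pool and aggregates signatures across datasets (union,
    intersect, or robust rank aggregation), then refines the signature by
    removing genes with high background (microenvironment) expression using a
    percentile-based signal-to-noise ratio. Includes a negative-binomial
    simulator with planted markers for end-to-end validation and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    edgeR,
    limma,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
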