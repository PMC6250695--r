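Package: revsig
Title: Connectivity Mapping and Cross-Species Reversal Analysis of
    Transcriptional Disease Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for connectivity-map style drug
    repurposing and treatment-reversal analysis of bulk transcriptomic
    data. Builds directional gene signatures from differential-expression
    tables or robust z-scored profiles, scores compound profiles against
    disease signatures with the weighted Kolmogorov-Smirnov connectivity
    statistic and a permutation null, tests cross-species signature
    concordance and reversal with Fisher's exact test over a mappable
    ortholog universe, quantifies per-pathway percent reversal of disease
    expression after treatment, and implements the accompanying
    histology (NAFLD activity score), qPCR (comparative Ct) and
    group-comparison endpoint statistics. Includes a seeded
    negative-binomial simulator that generates every input with known
    ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
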