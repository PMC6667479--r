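Package: circasplice
Title: Circadian Rhythm Detection and Time-Dependent Alternative Splicing
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting circadian oscillations in short expression
    time courses by harmonic (cosinor) regression with a period scan and a
    nonparametric rank companion test, quantifying time-dependent alternative
    splicing from probe-level inclusion/exclusion signals via percent
    spliced-in (PSI) statistics with binned pairwise contrasts, measuring
    cross-set interaction enrichment on labelled protein-interaction networks
    against a random-set resampling null, hypergeometric over-representation
    tests, qPCR 2^-ddCT quantification, and a synthetic-data generator that
    emulates the sampling design of circadian microarray time courses so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
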