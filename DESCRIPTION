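Package: cnacompare
Title: Comparative Copy-Number and TP53 Mutation Analysis of Breast Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel-convolution analysis of array-CGH log2-ratio profiles
    (per-tumor and per-group smoothed estimates, between-group signal-to-noise
    curves with class-label permutation FDR control, copy-number-aberration
    burden sweeps, and region-mean hierarchical clustering), together with
    rule-based classification of TP53 mutation strings (complex/truncating,
    hotspot, missense) and exact group statistics. Includes a synthetic
    aCGH cohort and mutation-table generator emulating a ~1 Mb BAC/PAC
    platform so every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
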