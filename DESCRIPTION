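Package: epicombi
Title: Drug-Combination Synergy Screening, Hit Prioritization, and
    Pan-Cancer Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-drug combination screens with the
    median-effect/combination-index (Chou-Talalay) framework: median-effect
    dose-response fitting from viability plates, combination-index profiles
    for constant-ratio series with synergy classification, multi-feature
    weighted prioritization of screen hits, a formula-defined impact score
    for knockdown screens, and pan-cancer differential-expression and
    survival meta-analysis (one-sided tests combined by Fisher's method,
    Cox proportional-hazards arms, sample deduplication for barcode-style
    cohorts, gene-set construction and over-representation testing). A
    synthetic-data module generates every input with known ground truth so
    the full pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
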