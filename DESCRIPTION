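Package: attnpharm
Title: Single-Unit Analysis of Attentional Modulation Under Local Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing single-unit extracellular recordings collected
    while a subject performs a spatial-attention task and a substance is
    pressure-injected near the recording site. Provides trial-aligned firing
    rate extraction and peristimulus time histograms, segmentation of sessions
    into control, injection, and recovery blocks from the injection timeline,
    two-stage cell inclusion criteria (data quality and injection
    responsiveness), attentional and injection modulation indices with percent
    conversions, and nonparametric population statistics including subgroup
    analysis and paired block comparisons. Includes a Poisson spike-train
    session generator with known attention gain and heterogeneous
    multiplicative injection effects, so the full pipeline can be exercised
    end-to-end and parameter recovery verified.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
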