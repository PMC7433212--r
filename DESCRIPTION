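Package: pancanSig
Title: Pan-Cancer Copy-Number and Expression Signature Analysis with
    Survival Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies putative loss- and gain-of-function pathway genes
    from GISTIC-style thresholded copy-number calls combined with
    tumor versus non-tumor differential expression across many cancer
    types, scores patients with gene-set pathway signatures, and
    evaluates prognostic impact with Kaplan-Meier curves, log-rank
    tests, Cox proportional-hazards regression, time-dependent ROC
    analysis, principal-coordinates ordination with PERMANOVA, and
    hypergeometric over-representation analysis against GMT gene-set
    libraries. Ships a synthetic multi-cancer cohort generator with
    planted copy-number and expression effects and score-linked
    proportional-hazards survival so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
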