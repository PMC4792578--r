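Package: reopair
Title: Rank-Based Gene-Pair Signatures for Prognosis and Treatment-Benefit
    Prediction
Version: 0.1.0
Authors@R:
    person("reopair", "developers", email = "reopair@example.org",
           role = c("aut", "cre"))
Description: Implements within-sample relative expression ordering (REO)
    analysis for transcriptomic cohorts: identification of gene pairs with
    stable orderings in normal tissue, cross-platform consistency testing,
    per-sample pathway disruption indexes, Cox proportional-hazards screening
    with Benjamini-Hochberg false-discovery control, forward-stepwise
    concordance-index selection of minimal gene-pair signatures under a
    zero-reversal classification rule, and sequential application of a
    drug-free prognostic signature and a treatment-benefit predictive
    signature to stratify patients into three groups. A fully parameterised
    survival-cohort simulator with ground-truth manifests makes the complete
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
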