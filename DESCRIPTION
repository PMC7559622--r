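Package: pocdassoc
Title: Reliable-Change Classification of Postoperative Cognitive
    Dysfunction and Single-SNP Case-Control Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control studies of postoperative cognitive
    dysfunction (POCD). Implements the reliable change index (RCI)
    classifier for a multi-test neuropsychological battery calibrated
    against a healthy control group (control-adjusted change scores,
    1.96-SD rule, two-of-six positivity), a single-SNP association
    engine covering allelic, additive, dominant and recessive genetic
    models with Woolf-type odds-ratio confidence intervals and
    Hardy-Weinberg equilibrium diagnostics, group-comparison summary
    tables (t-test and chi-square), and a synthetic cohort simulator
    with known ground truth for end-to-end validation of every stage.
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
    withr
Config/testthat/edition: 3
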