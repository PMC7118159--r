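Package: rbpath
Title: Pan-Cancer RB-Pathway Genetics and CDK4/6-RB Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing deregulation of the cyclin D-CDK4/6-RB axis
    across tumour cohorts: somatic alteration calling with co-occurrence and
    mutual-exclusivity odds-ratio tests, chromosome-arm dosage (cis) analysis
    of 13q loss, derivation and scoring of an integrated CDK4/6-RB expression
    signature from isogenic CDK4/6-inhibitor experiments, cross-cohort
    dosage differential expression with recurrence and cis/trans
    classification, bootstrap-thresholded signature-correlation mining with
    weighted pre-ranked gene set enrichment, and Kaplan-Meier stratification
    by signature score. Includes a synthetic-cohort generator with planted
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    mclust
Config/testthat/edition: 3
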