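Package: kgemr
Title: Knowledge-Graph Enrichment of Electronic Medical Record Vectors for
    Hospitalization Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bag-of-words plus bag-of-concepts vector representations of
    electronic medical records (EMRs), where the concept block is extracted from
    specialized drug and primary-care terminologies (ATC, ICPC-2, NDF-RT) and
    from cross-domain knowledge graphs (Wikidata-like and DBpedia-like RDF
    fixtures).  Concept features are denoised by L1-penalized selection run
    inside the inner loop of a nested cross-validation, and the contribution of
    each enrichment is assessed with pooled F1 across folds, per-fold metric
    averages, the variance-corrected dependent t-test for cross-validated
    metrics, and Krippendorff's alpha for annotator agreement.  A synthetic
    cohort generator with planted concept effects makes the whole pipeline
    testable without access to any clinical database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    ranger,
    e1071,
    pROC,
    jsonlite,
    yaml,
    stringi,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
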