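Package: ehrsubtype
Title: Data-Driven Disease Subtyping from Longitudinal Coded Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unsupervised subtyping of patients from longitudinal
    coded electronic health records. Prediagnostic event streams are tokenized
    by visit, age and calendar year, encoded with a small transformer trained
    with a masked-encounter objective and refined with a contrastive objective,
    and the resulting patient embeddings are clustered with K-means. The number
    of subtypes is selected by prediction strength, with silhouette,
    Davies-Bouldin, bootstrap adjusted Rand index, consensus-clustering PAC and
    cross-source ARI as supporting stability metrics. Downstream
    characterization covers comorbidity prevalence and weighted discriminative
    scores, symptom trajectories, cognitive-score trends, prototype patients,
    healthcare-utilization checks, five-year survival analyses (Kaplan-Meier,
    log-rank, adjusted Cox models) and genetic contrasts (polygenic-score
    t-tests, SNP dosage logistic regression, Fisher exact tests, carrier
    enrichment). A synthetic-cohort generator with planted subtype structure
    supports end-to-end testing without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    arrow
Config/testthat/edition: 3
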