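Package: leatsubtype
Title: Transcriptional Subtyping of Long-Term Epilepsy-Associated Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised transcriptional subtyping for long-term
    epilepsy-associated tumor (LEAT) cohorts: multi-dataset merging with
    empirical-Bayes (ComBat-style) batch correction, partitioning-around-medoids
    clustering with silhouette-based model selection and negative-silhouette
    core-sample filtering, subsampled consensus-clustering validation,
    nearest-shrunken-centroid signature genes with cross-validated gene
    ranking, permutation-based pre-ranked gene set enrichment analysis and
    per-sample gene set variation scores, and subgroup-stratified clinical and
    progression-free-survival statistics. Ships a multi-batch synthetic cohort
    generator with planted subgroups and outcome-coupled covariates for
    end-to-end validation, plus a packaged 18-patient clinical fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    survival,
    utils
Suggests:
    cluster,
    fgsea,
    jsonlite,
    mclust,
    optparse,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
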