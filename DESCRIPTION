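Package: radclust
Title: Harmonization and Unsupervised Clustering of MRI Radiomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for unsupervised subtyping of tumors from MRI radiomic
    feature matrices. Removes acquisition-protocol (scanner) effects from
    radiomic features with per-feature linear models gated by false discovery
    rate control, stratifies patients by K-medoids (PAM) clustering with a
    squared Euclidean distance, ranks cluster-driving features by a
    centroid-distance statistic, and associates the resulting clusters with
    survival, clinicopathological variables and somatic mutation frequencies.
    Ships a synthetic cohort generator with planted cluster structure, scanner
    confounding, cluster-dependent survival and mutation enrichment so that
    every stage of the pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
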