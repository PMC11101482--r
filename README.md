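# radclust

Harmonization and unsupervised clustering of MRI radiomic profiles, with
survival and radiogenomic association — an R implementation of a complete
radiomic subtyping pipeline for multi-scanner tumor cohorts (developed
around whole-volume cervical cancer MRI, but agnostic to the tumor type).

## What it does

Given a patient × feature radiomic matrix (293 features from T2-weighted,
high b-value DWI and ADC series), an acquisition-protocol table, a clinical
table and optionally a binary mutation matrix, the pipeline:

1. **Harmonizes** each feature against the acquisition protocol: a
   per-feature OLS model on voxel volume, voxel anisotropy, TR, TE, flip
   angle, averages, field strength, echo-train length and phase-encoding
   direction (plus highest b-value and number of b-values for
   diffusion-derived features). Features whose overall F-test survives
   Benjamini–Hochberg FDR at α = 0.05 are replaced by their residuals;
   every feature is then z-normalized.
2. **Clusters** patients by K-medoids (classical PAM, BUILD + SWAP,
   squared Euclidean distance, deterministic tie-breaks, seeded restarts)
   at a user-chosen K (default 3), renumbers clusters by ascending
   death-by-disease frequency, and re-tests the labels against every
   acquisition covariate.
3. **Ranks features** by the centroid-distance statistic
   FR_k = sqrt( Σ_{i<j} (μ_k(C_i) − μ_k(C_j))² ), flags the
   high-contribution intervals (I: FR > 1.85; II: 1.50 < FR < 1.85),
   attributes them to MR series and feature group, and runs a
   tumor-volume confound analysis (Spearman screen, rank comparison,
   volume's own rank, volume-by-cluster ANOVA).
4. **Associates clusters with outcome**: Kaplan–Meier / Mantel–Cox
   log-rank (overall and pairwise), Cox models unadjusted and adjusted for
   cluster (2/3 vs 1), FIGO stage (III/IV vs I/II) and age; chi-squared /
   Fisher and Mann–Whitney / Kruskal–Wallis clinicopathological
   comparisons; per-gene cluster-vs-rest Fisher tests with FDR and a
   pathway-level mutation summary.

A seeded **synthetic cohort generator** (`generate_cohort()`) reproduces
the statistical structure all of this assumes — planted cluster signal,
linear scanner confounding from jittered scanner profiles, cluster-dependent
exponential survival with uniform censoring, cluster-enriched mutations —
so the whole pipeline is testable without patient data.

## Worked example

```r
library(radclust)
b   <- generate_cohort(generator_config(seed = 42))  # 132 patients
res <- run_pipeline(b, k = 3, n_restarts = 5, seed = 42)
```

Output (as printed by the calls below):

```r
res$report_before$fraction   # "252/293 (86.0%)"  features protocol-associated
res$report_after$fraction    # "0/293 (0.0%)"     none after harmonization
table(res$clusters$labels)   #  1: 50   2: 57   3: 25
res$protocol_check$min_p     # 0.652  (no cluster–protocol association)
res$km$logrank_p             # 0.00144
res$cox_unadjusted[1, ]      # HR cluster 2/3 vs 1: 2.19 (0.94–5.15)
res$volume$volume_rank       # 218 of 293
head(res$ranking$table[, c("name", "series", "fr", "rank", "interval")])
#                                         name     series       fr rank interval
# 1           ADC_glrlm_RunLengthNonUniformity        ADC 2.273511    1        I
# 2 DWI_gldm_DependenceNonUniformityNormalized high-b DWI 2.259790    2        I
# 3                               DWI_glcm_Idn high-b DWI 2.188468    3        I
```

Reading: 86% of raw features carried scanner signal and none does after
harmonization; the three clusters are protocol-independent and differ in
disease-specific survival (log-rank p = 0.001), with the pooled high-risk
clusters at roughly twice the hazard of cluster 1; the cluster separation
is driven by texture features, not by tumor volume (rank 218/293).

Bundles round-trip through plain CSV/JSON via `write_bundle()` /
`read_bundle()`, and `inst/scripts/radclust-cli.R` exposes
`simulate` / `harmonize` / `cluster` / `rank` / `associate` subcommands for
shell use.

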