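# End-to-end pipeline over a cohort bundle.

#' Run the full radiomic profiling pipeline on a cohort
#'
#' Chains the stages: protocol harmonization (with before/after association
#' reports), PAM clustering at the user-set K, relabeling by death
#' frequency, protocol-independence re-test, FR feature ranking with the
#' tumor-volume confound analysis, Kaplan-Meier/log-rank and Cox survival
#' association, the clinicopathological comparison table, and (when a
#' mutation matrix is present) per-gene and pathway-level mutation tests.
#'
#' @param bundle A \code{cohort_bundle} (from [generate_cohort()] or
#'   [read_bundle()]).
#' @param k Number of clusters (default 3).
#' @param n_restarts PAM restarts.
#' @param seed Seed for clustering restarts.
#' @param alpha Significance/FDR level used throughout.
#' @return A list with elements \code{report_before}, \code{report_after},
#'   \code{harmonized}, \code{models}, \code{clusters}, \code{protocol_check},
#'   \code{k_diagnostics}, \code{fr}, \code{ranking}, \code{volume},
#'   \code{km}, \code{cox_unadjusted}, \code{cox_adjusted}, \code{clin},
#'   \code{mutation_tests}, \code{pathways}.
#' @examples
#' \donttest{
#' b <- generate_cohort(generator_config(n_patients = 80, seed = 11))
#' res <- run_pipeline(b, k = 3)
#' res$report_before$fraction
#' table(res$clusters$labels)
#' }
#' @export
run_pipeline <- function(bundle, k = 3, n_restarts = 5, seed = 1L,
                         alpha = 0.05) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  catalog <- build_catalog()
  cfg <- harmonization_config(alpha = alpha)

  report_before <- association_report(bundle$feature_matrix, bundle$protocol,
                                      catalog, cfg, "before harmonization")
  h <- harmonize(bundle$feature_matrix, bundle$protocol, catalog, cfg)
  report_after <- association_report(h$harmonized, bundle$protocol,
                                     catalog, cfg, "after harmonization")

  cl <- pam_cluster(h$harmonized, k = k, n_restarts = n_restarts,
                    seed = seed)
  cl <- relabel_by_outcome(cl, bundle$clinical)
  pc <- protocol_independence_check(cl, bundle$protocol, alpha)
  kd <- k_diagnostics(h$harmonized, k_range = 2:6, seed = seed)

  fr <- compute_fr(cl$centroids)
  ranking <- rank_and_summarize(fr, catalog, centroids = cl$centroids)
  volume <- volume_confound_analysis(h$harmonized, ranking, cl$labels,
                                     alpha = alpha)

  km <- kaplan_meier(bundle$clinical, cl$labels)
  cox_u <- cox_model(bundle$clinical, cl$labels, adjusted = FALSE)
  cox_a <- cox_model(bundle$clinical, cl$labels, adjusted = TRUE)
  clin <- clinicopathological_table(bundle$clinical, cl$labels)

  mut <- NULL; pw <- NULL
  if (!is.null(bundle$mutations)) {
    mut <- per_gene_mutation_test(bundle$mutations, cl$labels, alpha)
    pw <- pathway_mutation_summary(bundle$mutations, cl$labels)
  }

  list(report_before = report_before, report_after = report_after,
       harmonized = h$harmonized, models = h$models, clusters = cl,
       protocol_check = pc, k_diagnostics = kd, fr = fr, ranking = ranking,
       volume = volume, km = km, cox_unadjusted = cox_u,
       cox_adjusted = cox_a, clin = clin, mutation_tests = mut,
       pathways = pw)
}
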