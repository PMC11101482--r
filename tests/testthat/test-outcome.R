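test_that("KM estimator is a proper survival curve", {
  clin <- data.frame(dss_time = c(5, 10, 15, 20, 25),
                     dss_event = c(0, 0, 0, 0, 0),
                     figo_stage = factor(rep("II", 5),
                                         levels = c("IB", "II", "III", "IV")),
                     age = rep(50, 5))
  km <- kaplan_meier(clin, rep(1, 5))
  s <- summary(km$fit)
  expect_true(all(km$fit$surv == 1))          # no events: S(t) = 1
  expect_true(is.na(km$logrank_p))

  b <- small_bundle(n = 100, seed = 4)
  km2 <- kaplan_meier(b$clinical, b$truth$true_cluster)
  # per stratum: S non-increasing, starts at <= 1
  idx <- rep(seq_along(km2$fit$strata), km2$fit$strata)
  for (g in unique(idx)) {
    s_g <- km2$fit$surv[idx == g]
    expect_true(all(diff(s_g) <= 1e-12))
    expect_lte(s_g[1], 1)
  }
  expect_equal(nrow(km2$pairwise), 3)
})

test_that("log-rank statistic equals the hypergeometric oracle", {
  time <- c(3, 5, 7, 9, 11, 2, 4, 6, 8, 10)
  event <- c(1, 0, 1, 1, 0, 1, 1, 0, 1, 1)
  group <- rep(1:2, each = 5)
  clin <- data.frame(dss_time = time, dss_event = event)
  km <- kaplan_meier(clin, group)
  oracle <- logrank_oracle(time, event, group)
  expect_equal(km$logrank_chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(km$logrank_p, oracle$p, tolerance = 1e-10)
})

test_that("log-rank is well calibrated under a random split", {
  b <- generate_cohort(generator_config(
    n_patients = 120, seed = 17,
    hazard_per_cluster = c(2, 2, 2) * 1e-4))
  set.seed(5)
  ps <- replicate(100, {
    g <- sample(1:2, 120, replace = TRUE)
    kaplan_meier(b$clinical, g)$logrank_p
  })
  # nominal 5% rejection rate, binomial tolerance over 100 replicates
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps < 0.5), 0.3)
})

test_that("log-rank has power at a planted hazard ratio of 3", {
  hits <- vapply(1:20, function(s) {
    b <- generate_cohort(generator_config(
      n_patients = 150, seed = s,
      hazard_per_cluster = c(1, 3, 3) * 1e-4))
    kaplan_meier(b$clinical, b$truth$true_cluster)$logrank_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Cox model covers planted effects and respects invariances", {
  b <- generate_cohort(generator_config(n_patients = 150, seed = 3))
  labels <- b$truth$true_cluster
  cox <- cox_model(b$clinical, labels, adjusted = FALSE)
  expect_true(all(c("cluster23", "figo_advanced", "age") %in%
                    cox$covariate))
  expect_true(all(cox$ci_low <= cox$hr & cox$hr <= cox$ci_high))
  expect_true(all(cox$hr > 0))

  adj <- cox_model(b$clinical, labels, adjusted = TRUE)
  expect_equal(nrow(adj), 3)
  expect_equal(unique(adj$model), "adjusted")

  # exchangeable groups duplicated -> HR = 1
  clin2 <- rbind(b$clinical, b$clinical)
  lab2 <- rep(c(1, 2), each = nrow(b$clinical))
  hr <- cox_model(clin2, lab2)$hr[1]
  expect_equal(hr, 1, tolerance = 1e-6)

  # rescaling time units leaves the HR unchanged
  clin3 <- b$clinical
  clin3$dss_time <- clin3$dss_time * 7
  expect_equal(cox_model(clin3, labels)$hr[1], cox$hr[1], tolerance = 1e-8)

  expect_error(cox_model(within(b$clinical, dss_event <- 0), labels),
               "no events")
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  # fixture: [[3,0],[0,3]] -> two-sided p = 0.1
  tab <- matrix(c(3, 0, 0, 3), 2, 2)
  expect_equal(fisher_p_oracle(tab), 0.1, tolerance = 1e-12)
  expect_equal(stats::fisher.test(tab)$p.value, 0.1, tolerance = 1e-12)
  # random sweep of small tables
  set.seed(8)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 3), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_p_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("clinicopathological table picks the documented test per type", {
  b <- generate_cohort(generator_config(n_patients = 132, seed = 6))
  labels <- b$truth$true_cluster
  ct <- clinicopathological_table(b$clinical, labels)
  tab <- ct$table
  expect_equal(tab$test[tab$variable == "age"], "kruskal-wallis")
  expect_true(tab$test[tab$variable == "figo_stage"] %in%
                c("chi-square", "fisher"))
  # planted age shift across clusters is detected
  expect_lt(tab$p[tab$variable == "age"], 0.05)
  # two-cluster case switches to Mann-Whitney
  keep <- labels %in% 1:2
  ct2 <- clinicopathological_table(b$clinical[keep, ], labels[keep])
  expect_equal(ct2$table$test[ct2$table$variable == "age"], "mann-whitney")
  # constant variable skipped with a note
  clin <- b$clinical
  clin$histology <- factor("SCC", levels = levels(clin$histology))
  ct3 <- clinicopathological_table(clin, labels)
  expect_true("histology" %in% ct3$skipped)
})

test_that("per-gene mutation tests find planted enrichment, not noise", {
  b <- generate_cohort(generator_config(n_patients = 132, seed = 12))
  labels <- b$truth$true_cluster
  res <- per_gene_mutation_test(b$mutations, labels)
  enriched <- res$tests[res$tests$gene == "PIK3CA" &
                          res$tests$cluster == "3", ]
  expect_gt(enriched$freq_in, enriched$freq_rest)
  # an all-zero gene is untestable with p = 1
  m <- b$mutations
  m[, "NOTCH1"] <- 0L
  res2 <- per_gene_mutation_test(m, labels)
  z <- res2$tests[res2$tests$gene == "NOTCH1", ]
  expect_true(all(z$untestable))
  expect_true(all(z$p == 1))
  expect_equal(dim(res$frequency), c(20L, 3L))
})

test_that("planted enrichment is detected with power at the WES subset size", {
  hits <- vapply(1:15, function(s) {
    b <- generate_cohort(generator_config(
      n_patients = 65, seed = s,
      mutation = default_mutation_config(enrichment_odds = 8)))
    res <- per_gene_mutation_test(b$mutations, b$truth$true_cluster)
    any(res$tests$significant[res$tests$gene == "KMT2D" &
                                res$tests$cluster == "2"])
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("pathway aggregation reports per-cluster proportions", {
  b <- generate_cohort(generator_config(n_patients = 132, seed = 2))
  pw <- pathway_mutation_summary(b$mutations, b$truth$true_cluster)
  expect_true(all(c("prop_C1", "prop_C2", "prop_C3") %in% colnames(pw)))
  props <- as.matrix(pw[, c("prop_C1", "prop_C2", "prop_C3")])
  expect_true(all(props >= 0 & props <= 1))
  # PI3K pathway (enriched in cluster 3) has its maximum there
  expect_equal(unname(which.max(props[pw$pathway == "PI3K", ])), 3L)
})
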