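test_that("design matrices carry the series-appropriate covariates", {
  b <- small_bundle(n = 60, seed = 1)
  base <- build_design(b$protocol, "base")
  dwi <- build_design(b$protocol, "dwi")
  # 9 base acquisition parameters before encoding expansion; the DWI/ADC
  # design adds the highest b-value and the number of b-values
  expect_true(all(c("voxel_volume", "voxel_anisotropy", "repetition_time",
                    "echo_time", "flip_angle", "n_averages",
                    "field_strength_3T", "echo_train_length",
                    "phase_encoding_COL") %in% colnames(base)))
  expect_false(any(c("highest_b_value", "n_b_values") %in% colnames(base)))
  expect_true(all(c("highest_b_value", "n_b_values") %in% colnames(dwi)))
  expect_equal(ncol(dwi), ncol(base) + 2)
  expect_equal(qr(dwi)$rank, ncol(dwi))
})

test_that("rank-deficient designs are refused naming the collinear column", {
  b <- small_bundle(n = 60, seed = 1)
  p <- b$protocol
  p$echo_train_length <- 2 * p$echo_time        # force collinearity
  expect_error(build_design(p, "base"), "rank deficient")
  expect_error(build_design(p, "base"), "echo_train_length")
})

test_that("missing covariates are refused; harmonize can drop the patients", {
  b <- small_bundle(n = 60, seed = 4)
  p <- b$protocol
  p$echo_time[3] <- NA
  expect_error(build_design(p, "base"), "missing covariate")
  expect_warning(
    h <- harmonize(b$feature_matrix, p, drop_incomplete = TRUE),
    rownames(p)[3])
  expect_equal(nrow(h$harmonized), 59)
})

test_that("a noiseless linear feature recovers its coefficient exactly", {
  b <- small_bundle(n = 60, seed = 2)
  m <- b$feature_matrix
  m[, "T2WI_firstorder_Mean"] <- 3 * b$protocol$echo_time
  models <- fit_protocol_models(m, b$protocol)
  co <- models$coefficients$base[, "T2WI_firstorder_Mean"]
  expect_equal(unname(co["echo_time"]), 3, tolerance = 1e-8)
  expect_equal(unname(co["(Intercept)"]), 0, tolerance = 1e-6)
  expect_equal(unname(models$p_value["T2WI_firstorder_Mean"]), 0)
})

test_that("constant features get p = 1 and are never residualized", {
  b <- small_bundle(n = 60, seed = 2)
  m <- b$feature_matrix
  m[, "ADC_ngtdm_Busyness"] <- 5
  models <- fdr_gate(fit_protocol_models(m, b$protocol))
  expect_equal(unname(models$p_value["ADC_ngtdm_Busyness"]), 1)
  expect_false(models$flagged[["ADC_ngtdm_Busyness"]])
  # z-normalizing a constant column is undefined
  expect_error(residualize_and_znorm(m, models), "ADC_ngtdm_Busyness")
})

test_that("FDR gate agrees with the direct step-up inequality", {
  b <- small_bundle(n = 60, seed = 6)
  models <- fit_protocol_models(b$feature_matrix, b$protocol)
  for (alpha in c(0.01, 0.05, 0.2)) {
    gated <- fdr_gate(models, harmonization_config(alpha = alpha))
    expect_equal(unname(gated$flagged),
                 unname(bh_flags_oracle(models$p_value, alpha)))
  }
  # spot-check the step-up on a tiny fixed p-vector
  expect_equal(bh_flags_oracle(c(0.001, 0.002, 0.04, 0.9), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  fake <- models
  fake$p_value[] <- 1
  expect_equal(sum(fdr_gate(fake)$flagged), 0)
})

test_that("harmonized features are z-scored and orthogonal to the design", {
  b <- small_bundle(n = 80, seed = 3)
  h <- harmonize(b$feature_matrix, b$protocol)
  z <- h$harmonized
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-10))
  # flagged features: zero sample correlation with every design column
  models <- h$models
  flagged <- names(which(models$flagged))[1:10]
  for (f in flagged) {
    x <- models$designs[[models$design_of[match(f, models$feature_names)]]]
    for (j in setdiff(colnames(x), "(Intercept)")) {
      expect_lt(abs(cor(z[, f], x[, j])), 1e-10)
    }
  }
  # unflagged features are the plain z-score of the input
  un <- names(which(!models$flagged))
  if (length(un)) {
    f <- un[1]
    expect_equal(unname(z[, f]),
                 unname(scale(b$feature_matrix[, f])[, 1]),
                 tolerance = 1e-12)
  }
})

test_that("harmonization removes all protocol association and is idempotent", {
  b <- small_bundle(n = 80, seed = 3)
  h <- harmonize(b$feature_matrix, b$protocol)
  after <- association_report(h$harmonized, b$protocol,
                              stage_label = "after")
  expect_equal(after$n_significant, 0)
  expect_match(after$fraction, "^0/293 \\(0\\.0%\\)$")
  h2 <- harmonize(h$harmonized, b$protocol)
  expect_lt(max(abs(h2$harmonized - h$harmonized)), 1e-8)
})

test_that("planted scanner effects are detected with high power", {
  detected <- vapply(1:5, function(s) {
    b <- generate_cohort(generator_config(n_patients = 150, seed = s))
    planted <- rowSums(b$truth$planted_coefficients != 0) > 0
    rep <- association_report(b$feature_matrix, b$protocol)
    flags <- rep$table$significant
    sum(flags & planted) / sum(planted)
  }, numeric(1))
  expect_true(all(detected >= 0.9))
})
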