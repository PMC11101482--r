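test_that("well-separated 1-D groups are partitioned exactly", {
  x <- matrix(c(0, 0.1, 10, 10.1, 20, 20.1), ncol = 1)
  cl <- pam_cluster(x, k = 3)
  expect_equal(unname(cl$labels), c(1, 1, 2, 2, 3, 3))
  expect_equal(cl$total_cost, 3 * 0.1^2 / 2 * 2, tolerance = 1e-12)
})

test_that("degenerate K values behave as specified", {
  x <- matrix(rnorm(16), 8, 2)
  expect_error(pam_cluster(x, k = 9), "between 1 and")
  cl <- pam_cluster(x, k = 8)
  expect_equal(cl$total_cost, 0)
  expect_equal(sort(unname(cl$labels)), 1:8)
  cl1 <- pam_cluster(x, k = 1)
  expect_equal(unname(cl1$medoid_ids),
               unname(which.min(colSums(as.matrix(dist(x))^2))))
})

test_that("PAM attains the exhaustive medoid optimum on small instances", {
  set.seed(42)
  for (i in 1:12) {
    n <- sample(6:10, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    cl <- pam_cluster(x, k, n_restarts = 5, seed = i)
    expect_equal(cl$total_cost, pam_cost_oracle(x, k), tolerance = 1e-10)
  }
})

test_that("PAM matches the reference implementation on the same objective", {
  skip_if_not_installed("cluster")
  b <- small_bundle(n = 60, seed = 3)
  h <- harmonize(b$feature_matrix, b$protocol)
  mine <- pam_cluster(h$harmonized, 3, n_restarts = 5, seed = 1)
  d2 <- as.matrix(dist(h$harmonized))^2
  ref <- cluster::pam(stats::as.dist(d2), 3)
  ref_cost <- sum(apply(d2[, ref$id.med, drop = FALSE], 1, min))
  expect_equal(mine$total_cost, ref_cost, tolerance = 1e-8)
  expect_equal(adjusted_rand_index(mine$labels, ref$clustering), 1)
})

test_that("solution is locally optimal under single swaps", {
  b <- small_bundle(n = 40, seed = 5)
  h <- harmonize(b$feature_matrix, b$protocol)
  cl <- pam_cluster(h$harmonized, 3, seed = 1)
  d2 <- as.matrix(dist(h$harmonized))^2
  cost_of <- function(meds) sum(apply(d2[, meds, drop = FALSE], 1, min))
  for (mi in seq_along(cl$medoid_ids)) {
    for (h_ in setdiff(seq_len(nrow(d2)), cl$medoid_ids)) {
      alt <- cl$medoid_ids
      alt[mi] <- h_
      expect_gte(cost_of(alt), cl$total_cost - 1e-9)
    }
  }
})

test_that("centroid rows equal within-cluster feature means", {
  b <- small_bundle(n = 50, seed = 8)
  h <- harmonize(b$feature_matrix, b$protocol)
  cl <- pam_cluster(h$harmonized, 3, seed = 1)
  for (i in 1:3) {
    expect_equal(unname(cl$centroids[i, ]),
                 unname(colMeans(h$harmonized[cl$labels == i, ])))
  }
})

test_that("k diagnostics prefer the planted K at large separation", {
  hits <- vapply(1:3, function(s) {
    b <- generate_cohort(generator_config(
      n_patients = 120, seed = s, cluster_separation = 4.0,
      n_informative_features = 80))
    h <- harmonize(b$feature_matrix, b$protocol)
    kd <- k_diagnostics(h$harmonized, 2:6, seed = s, n_restarts = 3)
    c(kd$k[which.max(kd$calinski_harabasz)] == 3,
      kd$k[which.min(kd$davies_bouldin)] == 3,
      kd$k[which.max(kd$mean_silhouette)] == 3)
  }, logical(3))
  expect_true(all(hits))
})

test_that("a structureless blob yields near-zero silhouettes", {
  set.seed(1)
  x <- matrix(rnorm(100 * 5), 100, 5)
  kd <- k_diagnostics(x, 2:4, seed = 1)
  expect_true(all(abs(kd$mean_silhouette) < 0.25))
  expect_error(k_diagnostics(x, 1:3), "undefined at K = 1")
})

test_that("relabeling orders clusters by death frequency", {
  # raw clusters a,b,c with death frequencies 0.30, 0.05, 0.20 -> b,c,a
  labels <- rep(1:3, each = 20)
  ev <- c(rbinom(0, 1, 0), rep(c(1, 0), c(6, 14)),   # raw 1: 0.30
          rep(c(1, 0), c(1, 19)),                    # raw 2: 0.05
          rep(c(1, 0), c(4, 16)))                    # raw 3: 0.20
  res <- structure(list(labels = labels, medoid_ids = 1:3, k = 3,
                        total_cost = 0,
                        centroids = matrix(1:3, 3, 1)),
                   class = "cluster_result")
  clin <- data.frame(dss_event = ev)
  out <- relabel_by_outcome(res, clin)
  expect_equal(unname(out$relabel_map), c(3, 1, 2))
  f <- tapply(clin$dss_event, out$labels, mean)
  expect_true(all(diff(f) > 0))
  expect_equal(which.max(f), 3L, ignore_attr = TRUE)

  # ties keep original label order
  clin2 <- data.frame(dss_event = rep(0, 60))
  out2 <- relabel_by_outcome(res, clin2)
  expect_equal(unname(out2$relabel_map), 1:3)

  # invariance to raw label permutation: relabeled partition is identical
  perm <- c(2, 3, 1)
  res_p <- res
  res_p$labels <- perm[res$labels]
  res_p$centroids <- res$centroids[order(perm), , drop = FALSE]
  out_p <- relabel_by_outcome(res_p, clin)
  expect_equal(adjusted_rand_index(out$labels, out_p$labels), 1)
  expect_equal(unname(out_p$labels), unname(out$labels))
})

test_that("protocol independence check flags planted association only", {
  b <- small_bundle(n = 120, seed = 10)
  # labels copied from field strength -> that covariate must be flagged
  res <- structure(list(labels = as.integer(
    b$protocol$field_strength == 3.0) + 1L, k = 2), class = "cluster_result")
  chk <- protocol_independence_check(res, b$protocol)
  expect_true(chk$table$significant[chk$table$covariate == "field_strength"])
  # labels independent of protocol -> no significant covariate
  set.seed(99)
  res2 <- structure(list(labels = sample(1:3, 120, replace = TRUE), k = 3),
                    class = "cluster_result")
  chk2 <- protocol_independence_check(res2, b$protocol)
  expect_true(chk2$pass)
  expect_gt(chk2$min_p, 0)
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(7)
  for (i in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5 %% 2, (1:5 %% 2)[c(1, 2, 3, 4, 5)]), 1)
})
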