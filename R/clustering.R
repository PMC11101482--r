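# K-medoids patient stratification.
#
# Classical PAM (BUILD initialization followed by best-improvement SWAP) on a
# squared Euclidean dissimilarity, run on the harmonized (z-scored) feature
# matrix. All tie-breaks are by lowest index so results are deterministic
# given the seed controlling random restarts.

#' Partitioning around medoids with squared Euclidean distance
#'
#' Runs PAM on the rows of \code{x}: BUILD picks initial medoids greedily,
#' SWAP repeatedly applies the single medoid/non-medoid exchange that most
#' reduces the total cost (sum of squared Euclidean distances of every point
#' to its medoid) until no exchange improves it. Additional restarts use
#' random initial medoids; the solution with the lowest total cost wins.
#'
#' @param x Numeric matrix, patients in rows (typically harmonized features).
#' @param k Number of clusters (user decision; the pipeline default is 3).
#' @param n_restarts Number of PAM runs; the first uses \code{init},
#'   subsequent ones random initialization.
#' @param seed Seed controlling random restarts.
#' @param init \code{"BUILD"} (default) or \code{"random"} for the first run.
#' @return A list of class \code{cluster_result}: \code{labels} (1..k,
#'   numbered by ascending medoid index), \code{medoid_ids} (row indices),
#'   \code{total_cost}, \code{centroids} (k x features matrix of
#'   within-cluster means), \code{k}, and \code{relabel_map} (filled by
#'   [relabel_by_outcome()]).
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
#' pam_cluster(x, k = 2)$labels
#' @export
pam_cluster <- function(x, k, n_restarts = 1, seed = 1L,
                        init = c("BUILD", "random")) {
  init <- match.arg(init)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must be between 1 and the number of patients",
                           call. = FALSE)
  d2 <- as.matrix(stats::dist(x))^2
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    med0 <- if (r == 1 && init == "BUILD") .pam_build(d2, k)
            else sort(sample.int(n, k))
    sol <- .pam_swap(d2, med0)
    if (is.null(best) || sol$cost < best$cost - 1e-12) best <- sol
  }
  medoids <- sort(best$medoids)
  # nearest medoid, ties to the lowest medoid index
  dm <- d2[, medoids, drop = FALSE]
  labels <- max.col(-dm, ties.method = "first")
  names(labels) <- rownames(x)
  centroids <- .cluster_centroids(x, labels, k)
  structure(list(labels = labels, medoid_ids = medoids,
                 total_cost = best$cost, centroids = centroids, k = k,
                 relabel_map = NULL),
            class = "cluster_result")
}

.pam_build <- function(d2, k) {
  n <- nrow(d2)
  medoids <- which.min(colSums(d2))        # first medoid: 1-medoid optimum
  dn <- d2[, medoids]
  while (length(medoids) < k) {
    gain <- colSums(pmin(d2, dn) - dn)     # per-candidate cost change
    gain[medoids] <- Inf
    cand <- which.min(gain)                # which.min breaks ties low
    medoids <- c(medoids, cand)
    dn <- pmin(dn, d2[, cand])
  }
  medoids
}

.pam_swap <- function(d2, medoids) {
  n <- nrow(d2)
  k <- length(medoids)
  repeat {
    dm <- d2[, medoids, drop = FALSE]
    nearest <- max.col(-dm, ties.method = "first")
    dn <- dm[cbind(seq_len(n), nearest)]
    ds <- if (k > 1) apply(dm, 1, function(r) sort(r, partial = 2)[2])
          else rep(Inf, n)
    cost <- sum(dn)
    best_delta <- -1e-9; best_m <- 0L; best_h <- 0L
    nonmed <- setdiff(seq_len(n), medoids)
    for (mi in seq_len(k)) {
      owns <- nearest == mi
      for (h in nonmed) {
        dh <- d2[, h]
        newd <- ifelse(owns, pmin(ds, dh), pmin(dn, dh))
        delta <- sum(newd) - cost
        if (delta < best_delta - 1e-12) {
          best_delta <- delta; best_m <- mi; best_h <- h
        }
      }
    }
    if (best_m == 0L) return(list(medoids = medoids, cost = cost))
    medoids[best_m] <- best_h
  }
}

.cluster_centroids <- function(x, labels, k) {
  cent <- matrix(NA_real_, k, ncol(x),
                 dimnames = list(paste0("C", seq_len(k)), colnames(x)))
  for (i in seq_len(k)) {
    cent[i, ] <- colMeans(x[labels == i, , drop = FALSE])
  }
  cent
}

#' Cluster-count diagnostics
#'
#' Computes, for each candidate K, the Calinski-Harabasz score (higher
#' better), the Davies-Bouldin score (lower better) and the mean silhouette
#' width on the PAM squared Euclidean dissimilarity (higher better). These
#' are advisory only; the pipeline keeps K a user decision.
#'
#' @param x Harmonized feature matrix.
#' @param k_range Candidate K values, each in \[2, n-1\].
#' @param seed Seed passed to [pam_cluster()].
#' @param n_restarts Restarts per K.
#' @return Data frame with columns \code{k}, \code{calinski_harabasz},
#'   \code{davies_bouldin}, \code{mean_silhouette}.
#' @export
k_diagnostics <- function(x, k_range = 2:6, seed = 1L, n_restarts = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_diagnostics requires 2 <= K <= n-1 (silhouette/Davies-Bouldin ",
         "are undefined at K = 1)", call. = FALSE)
  d2 <- as.matrix(stats::dist(x))^2
  grand <- colMeans(x)
  res <- lapply(k_range, function(k) {
    cl <- pam_cluster(x, k, n_restarts = n_restarts, seed = seed)
    lab <- cl$labels
    cent <- cl$centroids
    sizes <- tabulate(lab, k)
    wss <- sum(vapply(seq_len(k), function(i)
      sum(sweep(x[lab == i, , drop = FALSE], 2, cent[i, ])^2), numeric(1)))
    bss <- sum(sizes * rowSums(sweep(cent, 2, grand)^2))
    ch <- (bss / (k - 1)) / (wss / (n - k))
    # Davies-Bouldin on centroid distances
    s <- vapply(seq_len(k), function(i)
      mean(sqrt(rowSums(sweep(x[lab == i, , drop = FALSE], 2,
                              cent[i, ])^2))), numeric(1))
    m <- as.matrix(stats::dist(cent))
    db <- mean(vapply(seq_len(k), function(i)
      max(((s[i] + s[-i]) / m[i, -i])), numeric(1)))
    data.frame(k = k, calinski_harabasz = ch, davies_bouldin = db,
               mean_silhouette = .mean_silhouette(d2, lab, k))
  })
  do.call(rbind, res)
}

.mean_silhouette <- function(d2, labels, k) {
  n <- nrow(d2)
  sizes <- tabulate(labels, k)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[li] == 1) { sil[i] <- 0; next }
    sums <- vapply(seq_len(k), function(c) sum(d2[i, labels == c]),
                   numeric(1))
    a <- sums[li] / (sizes[li] - 1)
    b <- min(sums[-li] / sizes[-li])
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

#' Relabel clusters by disease-specific death frequency
#'
#' Renumbers the clusters so that the death-by-disease frequency
#' (events / cluster size) increases with the cluster number: cluster 1
#' carries the lowest event frequency, the highest-risk cluster the highest.
#' Ties keep the original label order.
#'
#' @param result A [pam_cluster()] result.
#' @param clinical Clinical table with a \code{dss_event} column, aligned
#'   with the clustered matrix rows.
#' @return The \code{cluster_result} with relabeled \code{labels}, reordered
#'   \code{medoid_ids}/\code{centroids} and \code{relabel_map}
#'   (old label -> new label).
#' @export
relabel_by_outcome <- function(result, clinical) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(clinical$dss_event) || anyNA(clinical$dss_event))
    stop("dss_event must be available for all patients", call. = FALSE)
  k <- result$k
  freq <- vapply(seq_len(k), function(i)
    mean(clinical$dss_event[result$labels == i]), numeric(1))
  ord <- order(freq, seq_len(k))          # ascending risk, ties by old label
  map <- integer(k); map[ord] <- seq_len(k)
  nm <- names(result$labels)
  result$labels <- map[result$labels]
  names(result$labels) <- nm
  result$medoid_ids <- result$medoid_ids[ord]
  result$centroids <- result$centroids[ord, , drop = FALSE]
  rownames(result$centroids) <- paste0("C", seq_len(k))
  result$relabel_map <- stats::setNames(map, paste0("raw", seq_len(k)))
  result
}

#' Re-test clusters against acquisition parameters
#'
#' Tests each protocol covariate for association with the cluster labels:
#' chi-squared for categorical covariates (field strength, phase-encoding
#' direction, highest b-value and any factor/character column), one-way
#' ANOVA for continuous ones; p-values FDR-adjusted across covariates.
#' Constant covariates are skipped with a note. The check passes iff no
#' covariate is significant after adjustment.
#'
#' @param result A \code{cluster_result}.
#' @param protocol Protocol table aligned with the clustered rows.
#' @param alpha Significance level on FDR-adjusted p-values.
#' @return A list: \code{table} (covariate, test, p, adjusted p, significant),
#'   \code{pass}, \code{min_p} (smallest unadjusted p) and \code{skipped}.
#' @export
protocol_independence_check <- function(result, protocol, alpha = 0.05) {
  labels <- factor(result$labels)
  categorical <- c("field_strength", "phase_encoding_direction",
                   "highest_b_value")
  rows <- list(); skipped <- character()
  for (v in colnames(protocol)) {
    col <- protocol[[v]]
    if (length(unique(col)) < 2) { skipped <- c(skipped, v); next }
    is_cat <- v %in% categorical || is.character(col) || is.factor(col)
    if (is_cat) {
      p <- suppressWarnings(stats::chisq.test(table(factor(col),
                                                    labels))$p.value)
      test <- "chi-square"
    } else {
      p <- stats::anova(stats::lm(col ~ labels))[["Pr(>F)"]][1]
      test <- "anova"
    }
    rows[[v]] <- data.frame(covariate = v, test = test, p = p)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adjusted <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$p_adjusted <= alpha
  list(table = tab, pass = !any(tab$significant), min_p = min(tab$p),
       skipped = skipped)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), approximately 0 for
#' independent ones.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  total <- ch2(length(a))
  expected <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}
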