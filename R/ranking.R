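# Centroid-distance feature ranking.
#
# Per feature, FR is the Euclidean distance among the K cluster centroids:
# the square root of the sum, over unordered cluster pairs, of squared
# centroid differences. Because features are z-normalized before clustering,
# FR values are comparable across features and a descending sort ranks the
# features driving the cluster separation. Two high-contribution intervals
# are marked by fixed thresholds (interval I: FR > 1.85; interval II:
# 1.50 < FR < 1.85, strict inequalities — a feature exactly at a threshold
# falls outside both intervals).

#' Ranking configuration
#'
#' @param interval_1_threshold FR above this falls in interval I.
#' @param interval_2_lower Lower bound of interval II;
#'   interval II is \code{(interval_2_lower, interval_1_threshold)}.
#' @param method \code{"euclidean"} (default): FR is the root of the sum of
#'   squared pairwise centroid differences. \code{"signed-sum"}: sensitivity
#'   variant squaring the plain sum of pairwise differences, which allows
#'   sign cancellation and is kept only for comparison.
#' @return A list of class \code{ranking_config}.
#' @export
ranking_config <- function(interval_1_threshold = 1.85,
                           interval_2_lower = 1.50,
                           method = c("euclidean", "signed-sum")) {
  stopifnot(interval_2_lower < interval_1_threshold)
  structure(list(interval_1_threshold = interval_1_threshold,
                 interval_2_lower = interval_2_lower,
                 method = match.arg(method)),
            class = "ranking_config")
}

#' Compute the FR statistic per feature
#'
#' \deqn{FR_k = \sqrt{\sum_{i<j} (\mu_k(C_i) - \mu_k(C_j))^2}}
#' where \eqn{\mu_k(C_i)} is the centroid of feature \eqn{k} in cluster
#' \eqn{i}. Invariant to cluster label permutation; for K = 2 it reduces to
#' \eqn{|\mu_k(C_1) - \mu_k(C_2)|}.
#'
#' @param centroids K x features matrix of within-cluster feature means
#'   (from [pam_cluster()]), computed on z-normalized features.
#' @param method See [ranking_config()].
#' @return Named numeric vector of FR values.
#' @examples
#' compute_fr(matrix(c(0, 1, 2), 3, 1))  # sqrt(6)
#' @export
compute_fr <- function(centroids, method = c("euclidean", "signed-sum")) {
  method <- match.arg(method)
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k < 2) stop("FR requires at least 2 clusters", call. = FALSE)
  pairs <- utils::combn(k, 2)
  diffs <- centroids[pairs[1, ], , drop = FALSE] -
    centroids[pairs[2, ], , drop = FALSE]
  fr <- if (method == "euclidean") sqrt(colSums(diffs^2))
        else sqrt(colSums(diffs)^2)
  stats::setNames(fr, colnames(centroids))
}

.interval_of <- function(fr, config) {
  ifelse(fr > config$interval_1_threshold, "I",
         ifelse(fr > config$interval_2_lower &
                  fr < config$interval_1_threshold, "II", "none"))
}

#' Rank features by FR and summarize attribution
#'
#' Sorts FR descending (ties broken by catalog order, so rank 1 is the
#' feature most responsible for cluster separation), assigns the interval
#' labels, and summarizes interval membership by MR series and feature
#' group. Group-wise differences in ranking across the six non-shape
#' feature groups are compared with a Kruskal-Wallis rank test.
#'
#' @param fr Named FR vector from [compute_fr()].
#' @param catalog A [build_catalog()] catalog.
#' @param config A [ranking_config()].
#' @param centroids Optional centroid matrix to carry per-cluster centroid
#'   positions into the ranking table.
#' @return A list of class \code{feature_ranking}: \code{table} (name,
#'   series, group, fr, rank, interval, and per-cluster centroids when
#'   supplied), \code{interval_by_series}, \code{interval_by_group},
#'   \code{group_rank_test} (Kruskal-Wallis over non-shape groups).
#' @export
rank_and_summarize <- function(fr, catalog = build_catalog(),
                               config = ranking_config(),
                               centroids = NULL) {
  stopifnot(all(catalog$name %in% names(fr)))
  fr <- fr[catalog$name]
  ord <- order(-fr, seq_along(fr))
  rank <- integer(length(fr)); rank[ord] <- seq_along(fr)
  tab <- data.frame(name = catalog$name, series = catalog$series,
                    group = catalog$group, fr = unname(fr), rank = rank,
                    interval = .interval_of(unname(fr), config),
                    stringsAsFactors = FALSE)
  if (!is.null(centroids)) {
    cc <- t(centroids[, catalog$name, drop = FALSE])
    colnames(cc) <- paste0("centroid_C", seq_len(ncol(cc)))
    tab <- cbind(tab, cc)
  }
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  nonshape <- tab[tab$group != "shape", ]
  krusk <- stats::kruskal.test(nonshape$fr, factor(nonshape$group))
  structure(list(
    table = tab,
    interval_by_series = table(interval = tab$interval, series = tab$series),
    interval_by_group = table(interval = tab$interval, group = tab$group),
    group_rank_test = list(statistic = unname(krusk$statistic),
                           p = krusk$p.value),
    config = config), class = "feature_ranking")
}

#' Tumor-volume confound analysis
#'
#' Quantifies how much of the ranking could be driven by tumor volume:
#' Spearman correlation of every feature with the volume feature
#' (FDR-corrected), a Kruskal-Wallis comparison of FR values between
#' volume-associated and non-associated features, the FR rank of the volume
#' feature itself, and a one-way ANOVA of volume across clusters.
#'
#' @param harmonized Harmonized feature matrix.
#' @param ranking A [rank_and_summarize()] result.
#' @param labels Cluster labels aligned with \code{harmonized} rows.
#' @param volume_feature Name of the volume feature
#'   (default [volume_feature_name()]).
#' @param alpha FDR level for the Spearman screen.
#' @return A list: \code{n_volume_associated}, \code{fraction} (formatted),
#'   \code{spearman} (per-feature rho, p, adjusted p, flag),
#'   \code{rank_test_p} (FR of associated vs not, Kruskal-Wallis),
#'   \code{volume_rank}, \code{volume_anova_p} (cluster means of volume).
#' @export
volume_confound_analysis <- function(harmonized, ranking, labels,
                                     volume_feature = volume_feature_name(),
                                     alpha = 0.05) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (!volume_feature %in% colnames(harmonized))
    stop("volume feature ", volume_feature, " not in matrix", call. = FALSE)
  vol <- harmonized[, volume_feature]
  other <- setdiff(colnames(harmonized), volume_feature)
  sp <- vapply(other, function(f) {
    ct <- suppressWarnings(
      stats::cor.test(harmonized[, f], vol, method = "spearman",
                      exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }, numeric(2))
  spearman <- data.frame(name = other, rho = sp["rho", ], p = sp["p", ])
  spearman$p_adjusted <- stats::p.adjust(spearman$p, method = "BH")
  spearman$associated <- spearman$p_adjusted <= alpha
  rownames(spearman) <- NULL

  rt <- ranking$table
  fr_other <- rt$fr[match(other, rt$name)]
  assoc <- factor(spearman$associated, levels = c(FALSE, TRUE))
  rank_test_p <- if (nlevels(droplevels(assoc)) == 2)
    stats::kruskal.test(fr_other, assoc)$p.value else NA_real_

  volume_rank <- rt$rank[rt$name == volume_feature]
  volume_anova_p <- stats::anova(
    stats::lm(vol ~ factor(labels)))[["Pr(>F)"]][1]

  k <- sum(spearman$associated)
  m <- nrow(rt)
  list(n_volume_associated = k,
       fraction = sprintf("%d/%d (%.1f%%)", k, m, 100 * k / m),
       spearman = spearman, rank_test_p = rank_test_p,
       volume_rank = volume_rank, volume_anova_p = volume_anova_p)
}
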