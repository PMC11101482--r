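# Cluster-outcome association.
#
# Survival: Kaplan-Meier product-limit curves per cluster with Mantel-Cox
# log-rank comparisons (overall and pairwise), and Cox proportional-hazards
# models for disease-specific survival -- unadjusted per covariate and
# adjusted for the binary cluster contrast (2/3 vs 1), binary FIGO stage
# (III/IV vs I/II) and age in years. Clinicopathological variables are
# compared across clusters with chi-squared / Fisher exact (categorical) or
# Mann-Whitney / Kruskal-Wallis (continuous) tests. Mutation frequencies are
# compared per gene with cluster-vs-rest Fisher tests under FDR control,
# plus a pathway-level aggregation.

.surv_frame <- function(clinical, labels) {
  stopifnot(nrow(clinical) == length(labels))
  n <- nrow(clinical)
  data.frame(dss_time = clinical$dss_time,
             dss_event = clinical$dss_event,
             cluster = factor(labels),
             cluster23 = as.integer(labels >= 2),
             figo_advanced = if (is.null(clinical$figo_stage))
               rep(NA_integer_, n) else
               as.integer(clinical$figo_stage %in% c("III", "IV")),
             age = if (is.null(clinical$age)) rep(NA_real_, n)
               else clinical$age)
}

#' Kaplan-Meier curves and log-rank tests by cluster
#'
#' Product-limit survival estimates per group with an overall Mantel-Cox
#' log-rank test and all pairwise group comparisons (unadjusted, as in
#' per-pair survival displays; adjust externally if desired).
#'
#' @param clinical Clinical table with \code{dss_time} (days) and
#'   \code{dss_event} (1 = death from disease).
#' @param labels Group (cluster) labels aligned with \code{clinical} rows.
#' @return A list: \code{fit} (a [survival::survfit] object),
#'   \code{logrank_p} (overall), \code{logrank_chisq}, and \code{pairwise}
#'   (data frame group1, group2, p).
#' @export
kaplan_meier <- function(clinical, labels) {
  df <- .surv_frame(clinical, labels)
  fit <- survival::survfit(survival::Surv(dss_time, dss_event) ~ cluster,
                           data = df)
  if (sum(df$dss_event) == 0)
    return(list(fit = fit, logrank_p = NA_real_, logrank_chisq = NA_real_,
                pairwise = NULL,
                note = "no events: log-rank not computable"))
  sd0 <- survival::survdiff(survival::Surv(dss_time, dss_event) ~ cluster,
                            data = df)
  groups <- levels(df$cluster)
  pw <- NULL
  if (length(groups) > 2) {
    combs <- utils::combn(groups, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      sub <- df[df$cluster %in% combs[, i], ]
      sub$cluster <- droplevels(sub$cluster)
      p <- if (sum(sub$dss_event) == 0) NA_real_ else
        survival::survdiff(survival::Surv(dss_time, dss_event) ~ cluster,
                           data = sub)$pvalue
      data.frame(group1 = combs[1, i], group2 = combs[2, i], p = p)
    }))
  }
  list(fit = fit, logrank_p = sd0$pvalue, logrank_chisq = unname(sd0$chisq),
       pairwise = pw)
}

#' Cox proportional-hazards models for disease-specific survival
#'
#' Fits either unadjusted single-covariate models or the adjusted model with
#' cluster (2/3 vs 1), FIGO stage (III/IV vs I/II) and age (years) entered
#' simultaneously. Ties are handled with the Breslow approximation by
#' default (Efron available).
#'
#' @param clinical Clinical table (needs \code{dss_time}, \code{dss_event},
#'   \code{figo_stage}, \code{age}).
#' @param labels Cluster labels (1..K); the cluster covariate is the binary
#'   contrast clusters >= 2 versus cluster 1.
#' @param adjusted Logical; fit the multivariable model.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @return A data frame with one row per covariate: \code{hr}, \code{ci_low},
#'   \code{ci_high} (Wald 95\%), \code{p}, \code{model}.
#' @export
cox_model <- function(clinical, labels, adjusted = FALSE,
                      ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  df <- .surv_frame(clinical, labels)
  keep <- stats::complete.cases(df)
  df <- df[keep, ]
  if (sum(df$dss_event) == 0) stop("no events: Cox model undefined",
                                   call. = FALSE)
  covs <- c("cluster23", "figo_advanced", "age")
  fit_one <- function(formula, model_label) {
    fit <- survival::coxph(formula, data = df, ties = ties)
    s <- summary(fit)
    data.frame(covariate = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               ci_low = s$conf.int[, "lower .95"],
               ci_high = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               model = model_label, row.names = NULL)
  }
  if (adjusted) {
    fit_one(survival::Surv(dss_time, dss_event) ~ cluster23 +
              figo_advanced + age, "adjusted")
  } else {
    do.call(rbind, lapply(covs, function(v)
      fit_one(stats::as.formula(
        paste("survival::Surv(dss_time, dss_event) ~", v)), "unadjusted")))
  }
}

# expected counts of a contingency table under independence
.expected_counts <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Clinicopathological comparison across clusters
#'
#' Per declared variable: categorical variables are tested with Pearson's
#' chi-squared, switching to Fisher's exact test when any expected cell
#' count is below 5 (exact for 2x2; the network/Monte-Carlo exact variant
#' for larger tables); continuous variables with Mann-Whitney (2 clusters)
#' or Kruskal-Wallis (3+). Constant variables are skipped with a note.
#'
#' @param clinical Clinical table.
#' @param labels Cluster labels.
#' @param variables Named character vector: variable name ->
#'   \code{"categorical"} or \code{"continuous"}. Defaults to the bundled
#'   clinical schema (FIGO stage, histology categorical; age, tumor
#'   diameter continuous).
#' @return A list: \code{table} (variable, test, statistic, p),
#'   \code{details} (per-variable contingency tables or group medians) and
#'   \code{skipped}.
#' @export
clinicopathological_table <- function(clinical, labels,
                                      variables = c(
                                        figo_stage = "categorical",
                                        histology = "categorical",
                                        age = "continuous",
                                        max_tumor_diameter = "continuous")) {
  cl <- factor(labels)
  rows <- list(); details <- list(); skipped <- character()
  for (v in names(variables)) {
    col <- clinical[[v]]
    if (is.null(col)) stop("clinical table has no column ", v, call. = FALSE)
    ok <- !is.na(col)
    if (length(unique(col[ok])) < 2) { skipped <- c(skipped, v); next }
    if (variables[[v]] == "categorical") {
      tab <- table(droplevels(factor(col[ok])), droplevels(cl[ok]))
      small <- any(.expected_counts(tab) < 5)
      if (small) {
        ft <- stats::fisher.test(tab, simulate.p.value = prod(dim(tab)) > 4,
                                 B = 10000)
        rows[[v]] <- data.frame(variable = v, test = "fisher",
                                statistic = NA_real_, p = ft$p.value)
      } else {
        ct <- stats::chisq.test(tab)
        rows[[v]] <- data.frame(variable = v, test = "chi-square",
                                statistic = unname(ct$statistic),
                                p = ct$p.value)
      }
      pct <- sweep(tab, 2, colSums(tab), "/") * 100
      details[[v]] <- list(counts = tab, percent = round(pct, 1))
    } else {
      if (nlevels(droplevels(cl[ok])) == 2) {
        wt <- stats::wilcox.test(col[ok] ~ droplevels(cl[ok]))
        rows[[v]] <- data.frame(variable = v, test = "mann-whitney",
                                statistic = unname(wt$statistic),
                                p = wt$p.value)
      } else {
        kt <- stats::kruskal.test(col[ok], cl[ok])
        rows[[v]] <- data.frame(variable = v, test = "kruskal-wallis",
                                statistic = unname(kt$statistic),
                                p = kt$p.value)
      }
      details[[v]] <- do.call(rbind, lapply(levels(cl), function(g)
        data.frame(cluster = g,
                   median = stats::median(col[ok & cl == g]),
                   min = min(col[ok & cl == g]),
                   max = max(col[ok & cl == g]))))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, details = details, skipped = skipped)
}

#' Per-gene mutation frequency comparison across clusters
#'
#' For each gene and each cluster, tests mutated/wild-type against the
#' pooled remaining clusters with Fisher's exact test (2x2), FDR-adjusted
#' across all gene-cluster tests. Genes mutated in no patient are reported
#' untestable with p = 1.
#'
#' @param mutations Binary patients x genes matrix.
#' @param labels Cluster labels aligned with the matrix rows.
#' @param alpha FDR level.
#' @return A list: \code{tests} (gene, cluster, frequencies, p, adjusted p,
#'   significant, untestable) and \code{frequency} (genes x clusters
#'   mutation-frequency matrix, oncoplot-style input).
#' @export
per_gene_mutation_test <- function(mutations, labels, alpha = 0.05) {
  stopifnot(nrow(mutations) == length(labels))
  cl <- factor(labels)
  ks <- levels(cl)
  freq <- sapply(ks, function(k)
    colMeans(mutations[cl == k, , drop = FALSE]))
  rows <- list()
  for (g in colnames(mutations)) {
    mut <- mutations[, g]
    untestable <- sum(mut) == 0
    for (k in ks) {
      inK <- cl == k
      p <- if (untestable) 1 else
        stats::fisher.test(matrix(c(sum(mut[inK]), sum(!mut[inK]),
                                    sum(mut[!inK]), sum(!mut[!inK])),
                                  2, 2))$p.value
      rows[[paste(g, k)]] <- data.frame(
        gene = g, cluster = k,
        freq_in = mean(mut[inK]), freq_rest = mean(mut[!inK]),
        p = p, untestable = untestable)
    }
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  tests$p_adjusted <- stats::p.adjust(tests$p, method = "BH")
  tests$significant <- tests$p_adjusted <= alpha & !tests$untestable
  list(tests = tests, frequency = freq)
}

#' Default oncogenic-pathway map for the bundled gene panel
#'
#' @return Named list mapping pathway name to member genes.
#' @export
default_pathway_map <- function() {
  list(
    "PI3K" = c("PIK3CA", "PTEN", "STK11"),
    "RTK-RAS" = c("KRAS", "ERBB2", "MAPK1"),
    "p53-cell cycle" = c("TP53", "RB1", "FBXW7", "CASP8"),
    "chromatin" = c("KMT2D", "ARID1A", "EP300", "CREBBP"),
    "NOTCH" = c("NOTCH1"),
    "TGF-beta" = c("SMAD4", "TGFBR2"),
    "other" = c("DDX3X", "NFE2L2", "HLA-B"))
}

#' Pathway-level mutation aggregation by cluster
#'
#' For each pathway, the proportion of patients per cluster carrying at
#' least one mutation in a member gene, compared across clusters by
#' chi-squared test.
#'
#' @param mutations Binary patients x genes matrix.
#' @param labels Cluster labels.
#' @param pathway_map Named list pathway -> gene names
#'   (default [default_pathway_map()]).
#' @return Data frame: pathway, per-cluster proportions, p.
#' @export
pathway_mutation_summary <- function(mutations, labels,
                                     pathway_map = default_pathway_map()) {
  cl <- factor(labels)
  ks <- levels(cl)
  rows <- lapply(names(pathway_map), function(pw) {
    genes <- intersect(pathway_map[[pw]], colnames(mutations))
    if (!length(genes)) return(NULL)
    hit <- as.integer(rowSums(mutations[, genes, drop = FALSE]) > 0)
    props <- vapply(ks, function(k) mean(hit[cl == k]), numeric(1))
    p <- if (length(unique(hit)) < 2) NA_real_ else
      suppressWarnings(stats::chisq.test(table(hit, cl))$p.value)
    out <- data.frame(pathway = pw, t(props), p = p)
    names(out)[2:(1 + length(ks))] <- paste0("prop_C", ks)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
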