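# Protocol harmonization.
#
# Each radiomic feature is regressed on the acquisition-protocol covariates;
# an overall F-test per feature, corrected across features by
# Benjamini-Hochberg FDR, decides whether the protocol explains the feature.
# Significant features are replaced by their OLS residuals; every feature is
# then z-normalized. DWI- and ADC-derived features additionally receive the
# two diffusion covariates (highest b-value, number of b-values) in their
# design.

#' Harmonization configuration
#'
#' @param alpha FDR level of the gate (default 0.05).
#' @param fdr_method Multiple-testing method passed to [stats::p.adjust()]
#'   (default \code{"BH"}, the Benjamini-Hochberg step-up).
#' @return A list of class \code{harmonization_config}.
#' @export
harmonization_config <- function(alpha = 0.05, fdr_method = "BH") {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, fdr_method = fdr_method),
            class = "harmonization_config")
}

#' Build a protocol design matrix
#'
#' Encodes the acquisition covariates for OLS: continuous covariates as-is,
#' field strength as a 3.0 T indicator, phase-encoding direction one-hot with
#' the first observed level as reference, plus an intercept. For DWI/ADC
#' feature designs (\code{type = "dwi"}) the highest b-value and the number
#' of b-values are appended.
#'
#' @param protocol Protocol table (one row per patient).
#' @param type \code{"base"} (shape and T2WI features) or \code{"dwi"}.
#' @return Numeric design matrix with named columns, full column rank.
#' @export
build_design <- function(protocol, type = c("base", "dwi")) {
  type <- match.arg(type)
  need <- c("voxel_volume", "voxel_anisotropy", "repetition_time",
            "echo_time", "flip_angle", "n_averages", "field_strength",
            "echo_train_length", "phase_encoding_direction")
  if (type == "dwi") need <- c(need, "highest_b_value", "n_b_values")
  miss <- setdiff(need, colnames(protocol))
  if (length(miss))
    stop("protocol table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(protocol[, need]))
    stop("protocol table contains missing covariate values; ",
         "drop incomplete patients first (see harmonize(drop_incomplete=))",
         call. = FALSE)
  pe <- as.factor(as.character(protocol$phase_encoding_direction))
  pe <- factor(pe, levels = unique(as.character(protocol$phase_encoding_direction)))
  pe_cols <- NULL
  if (nlevels(pe) > 1) {
    pe_cols <- sapply(levels(pe)[-1], function(l) as.numeric(pe == l))
    if (is.null(dim(pe_cols))) pe_cols <- matrix(pe_cols, ncol = 1)
    colnames(pe_cols) <- paste0("phase_encoding_", levels(pe)[-1])
  }
  x <- cbind(
    `(Intercept)` = 1,
    voxel_volume = protocol$voxel_volume,
    voxel_anisotropy = protocol$voxel_anisotropy,
    repetition_time = protocol$repetition_time,
    echo_time = protocol$echo_time,
    flip_angle = protocol$flip_angle,
    n_averages = protocol$n_averages,
    field_strength_3T = as.numeric(protocol$field_strength == 3.0),
    echo_train_length = protocol$echo_train_length)
  if (!is.null(pe_cols)) x <- cbind(x, pe_cols)
  if (type == "dwi")
    x <- cbind(x, highest_b_value = protocol$highest_b_value,
               n_b_values = protocol$n_b_values)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("protocol design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(x) <- rownames(protocol)
  x
}

# batch OLS of Y (n x m) on X via one QR; returns coefficients, fitted
# values and the overall F-test p-value per column of Y
.batch_ols <- function(x, y) {
  qx <- qr(x)
  coef <- qr.coef(qx, y)
  fitted <- x %*% coef
  n <- nrow(x); q <- ncol(x)
  rss <- colSums((y - fitted)^2)
  tss <- colSums(sweep(y, 2, colMeans(y))^2)
  constant <- tss < 1e-12
  fstat <- ((tss - rss) / (q - 1)) / (rss / (n - q))
  p <- stats::pf(fstat, q - 1, n - q, lower.tail = FALSE)
  p[rss < 1e-12 & !constant] <- 0   # perfect fit
  p[constant] <- 1                  # constant feature: nothing to explain
  list(coef = coef, fitted = fitted, p = p,
       sigma = sqrt(rss / pmax(1, n - q)), constant = constant)
}

#' Fit per-feature protocol models
#'
#' Fits one ordinary-least-squares model per radiomic feature with the
#' feature as outcome and the protocol design as explanatory variables.
#' Features derived from DWI or ADC series get the extended design with the
#' two diffusion covariates. The overall model F-test p-value is stored per
#' feature; constant features get p = 1 and are never residualized.
#'
#' @param matrix Patient x feature matrix with catalog column names.
#' @param protocol Protocol table aligned with \code{matrix} rows.
#' @param catalog A [build_catalog()] catalog.
#' @param config A [harmonization_config()].
#' @return An object of class \code{harmonization_models}: designs, per-design
#'   coefficient matrices, per-feature p-values and residual SDs.
#' @export
fit_protocol_models <- function(matrix, protocol,
                                catalog = build_catalog(),
                                config = harmonization_config()) {
  v <- validate_matrix(matrix, catalog)
  if (!v$pass)
    stop("feature matrix does not match catalog; missing: ",
         paste(utils::head(v$missing, 5), collapse = ", "),
         if (length(v$extra)) paste0("; extra: ",
           paste(utils::head(v$extra, 5), collapse = ", ")), call. = FALSE)
  if (nrow(matrix) != nrow(protocol))
    stop("matrix and protocol have different numbers of patients",
         call. = FALSE)
  matrix <- matrix[, catalog$name, drop = FALSE]
  series <- catalog$series
  is_dwi <- series %in% c("high-b DWI", "ADC")
  designs <- list(base = build_design(protocol, "base"),
                  dwi = build_design(protocol, "dwi"))
  design_of <- ifelse(is_dwi, "dwi", "base")

  p_value <- numeric(ncol(matrix)); names(p_value) <- catalog$name
  sigma <- p_value
  constant <- logical(ncol(matrix)); names(constant) <- catalog$name
  coefs <- list()
  for (d in c("base", "dwi")) {
    idx <- which(design_of == d)
    if (!length(idx)) next
    fit <- .batch_ols(designs[[d]], matrix[, idx, drop = FALSE])
    p_value[idx] <- fit$p
    sigma[idx] <- fit$sigma
    constant[idx] <- fit$constant
    coefs[[d]] <- fit$coef
  }
  structure(list(designs = designs, design_of = design_of,
                 coefficients = coefs, p_value = p_value, sigma = sigma,
                 constant = constant, config = config,
                 feature_names = catalog$name,
                 flagged = NULL, p_adjusted = NULL),
            class = "harmonization_models")
}

#' FDR gate on fitted protocol models
#'
#' Adjusts the per-feature overall-model p-values across features and flags
#' the features whose adjusted p-value is at or below \code{config$alpha};
#' only flagged features are residualized.
#'
#' @param models A [fit_protocol_models()] result.
#' @param config A [harmonization_config()]; defaults to the one stored in
#'   \code{models}.
#' @return \code{models} with \code{p_adjusted} and logical \code{flagged}
#'   filled in.
#' @export
fdr_gate <- function(models, config = models$config) {
  stopifnot(inherits(models, "harmonization_models"))
  models$p_adjusted <- stats::p.adjust(models$p_value,
                                       method = config$fdr_method)
  models$flagged <- models$p_adjusted <= config$alpha & !models$constant
  models$config <- config
  models
}

#' Residualize flagged features and z-normalize
#'
#' For each FDR-flagged feature, subtracts the full linear prediction
#' (including intercept) of its protocol model; unflagged features are left
#' as-is. Every feature is then z-normalized (mean 0, SD 1). The subsequent
#' z-normalization makes the intercept handling immaterial.
#'
#' @param matrix The matrix the models were fitted on.
#' @param models A gated [fdr_gate()] model set.
#' @return The harmonized matrix: every column has mean 0 and SD 1; flagged
#'   columns are orthogonal to their design columns. Attributes
#'   \code{znorm_mean}/\code{znorm_sd} record the normalization.
#' @export
residualize_and_znorm <- function(matrix, models) {
  stopifnot(inherits(models, "harmonization_models"))
  if (is.null(models$flagged))
    stop("models have not been FDR-gated; call fdr_gate() first",
         call. = FALSE)
  matrix <- matrix[, models$feature_names, drop = FALSE]
  out <- matrix
  for (d in names(models$coefficients)) {
    idx <- which(models$design_of == d & models$flagged)
    if (!length(idx)) next
    feat <- models$feature_names[idx]
    fitted <- models$designs[[d]] %*%
      models$coefficients[[d]][, feat, drop = FALSE]
    out[, feat] <- matrix[, feat, drop = FALSE] - fitted
  }
  mu <- colMeans(out)
  sd <- apply(out, 2, stats::sd)
  zero <- sd < 1e-12
  if (any(zero))
    stop("zero-variance column(s) after residualization: ",
         paste(models$feature_names[zero], collapse = ", "), call. = FALSE)
  out <- sweep(sweep(out, 2, mu), 2, sd, "/")
  attr(out, "znorm_mean") <- mu
  attr(out, "znorm_sd") <- sd
  out
}

#' Report protocol association of a feature matrix
#'
#' Refits the per-feature protocol models and reports how many features are
#' FDR-significant at the configured level; used before harmonization (to
#' quantify scanner confounding) and after (to verify none remains).
#'
#' @inheritParams fit_protocol_models
#' @param stage_label Free-text label stored in the report (e.g.
#'   \code{"before"} / \code{"after"}).
#' @return A list with \code{stage}, \code{n_significant}, \code{n_features},
#'   \code{fraction} (formatted \code{"k/m (xx.x\%)"}) and a per-feature
#'   \code{table} (name, p, adjusted p, flag).
#' @export
association_report <- function(matrix, protocol,
                               catalog = build_catalog(),
                               config = harmonization_config(),
                               stage_label = "") {
  models <- fdr_gate(fit_protocol_models(matrix, protocol, catalog, config))
  k <- sum(models$flagged)
  m <- length(models$flagged)
  list(stage = stage_label,
       n_significant = k, n_features = m,
       fraction = sprintf("%d/%d (%.1f%%)", k, m, 100 * k / m),
       table = data.frame(name = models$feature_names,
                          p = unname(models$p_value),
                          p_adjusted = unname(models$p_adjusted),
                          significant = unname(models$flagged)))
}

#' Harmonize a radiomic feature matrix against acquisition protocol
#'
#' Convenience wrapper: fit per-feature protocol models, apply the FDR gate,
#' residualize flagged features and z-normalize all features.
#'
#' @inheritParams fit_protocol_models
#' @param drop_incomplete Drop patients with missing protocol covariates
#'   (with a warning naming them) instead of refusing.
#' @return A list with \code{harmonized} (the z-normalized matrix),
#'   \code{models} (gated model set) and \code{n_significant} (features
#'   flagged before harmonization).
#' @examples
#' b <- generate_cohort(generator_config(n_patients = 80, seed = 3))
#' h <- harmonize(b$feature_matrix, b$protocol)
#' h$n_significant
#' @export
harmonize <- function(matrix, protocol, catalog = build_catalog(),
                      config = harmonization_config(),
                      drop_incomplete = FALSE) {
  if (drop_incomplete) {
    bad <- !stats::complete.cases(protocol)
    if (any(bad)) {
      warning("dropping ", sum(bad), " patient(s) with incomplete protocol: ",
              paste(rownames(protocol)[bad], collapse = ", "))
      matrix <- matrix[!bad, , drop = FALSE]
      protocol <- protocol[!bad, , drop = FALSE]
    }
  }
  models <- fdr_gate(fit_protocol_models(matrix, protocol, catalog, config))
  harmonized <- residualize_and_znorm(matrix, models)
  list(harmonized = harmonized, models = models,
       n_significant = sum(models$flagged))
}
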