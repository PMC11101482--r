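# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# patient x feature radiomic matrix carrying a planted cluster signal plus
# linear acquisition-protocol (scanner) effects and Gaussian noise; an
# acquisition-protocol table drawn from a small number of jittered scanner
# profiles; a clinical table with cluster-dependent survival, age, stage and
# histology; and an optional sparse mutation matrix with cluster-enriched
# genes. Ground truth (labels, informative features, planted coefficients,
# planted hazards) travels with the bundle for verification.

# covariates that can carry planted scanner effects; the last two only apply
# to DWI/ADC-derived features
.plant_covariates <- c("voxel_volume", "voxel_anisotropy", "repetition_time",
                       "echo_time", "flip_angle", "n_averages",
                       "echo_train_length", "field_strength_3T",
                       "highest_b_value", "n_b_values")

#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters controlling cohort generation. The
#' defaults template a 132-patient cohort split 52/46/34 across three
#' clusters, with 30 informative features separated by 2 within-cluster SD,
#' scanner effects on 85\% of the features, exponential disease-specific
#' survival with the lowest hazard in cluster 1, and a 20-gene mutation panel
#' with cluster-enriched genes.
#'
#' @param n_patients Number of patients.
#' @param n_features Number of radiomic features (must equal the catalog size
#'   when \code{catalog_names = TRUE}).
#' @param n_clusters Number of planted clusters K.
#' @param cluster_proportions Simplex vector of length \code{n_clusters}.
#' @param n_informative_features Number of features carrying cluster signal.
#' @param cluster_separation Distance between consecutive cluster means per
#'   informative feature, in units of the within-cluster SD.
#' @param scanner_effect_fraction Fraction of features receiving planted
#'   protocol effects.
#' @param scanner_effect_scale SD of the planted protocol coefficients
#'   (per standardized covariate, in feature-SD units).
#' @param noise_sd Residual (within-cluster) SD of each feature.
#' @param n_scanner_profiles Number of discrete scanner profiles the protocol
#'   table is sampled from before per-patient jitter.
#' @param hazard_per_cluster Exponential event rates (per day), one per
#'   cluster; cluster 1 should be lowest for an ordered risk structure.
#' @param censoring_max_days Administrative censoring drawn uniformly on
#'   (1, \code{censoring_max_days}) days.
#' @param mutation Either \code{NULL} (no mutation matrix) or a list with
#'   \code{genes} (character), \code{baseline_rate} (per-gene Bernoulli rate),
#'   \code{enriched} (named list, cluster index -> gene names) and
#'   \code{enrichment_odds} (odds multiplier for enriched genes).
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A validated list of class \code{generator_config}.
#' @export
generator_config <- function(n_patients = 132,
                             n_features = 293,
                             n_clusters = 3,
                             cluster_proportions = c(52, 46, 34) / 132,
                             n_informative_features = 30,
                             cluster_separation = 2.0,
                             scanner_effect_fraction = 0.85,
                             scanner_effect_scale = 0.5,
                             noise_sd = 1.0,
                             n_scanner_profiles = 4,
                             hazard_per_cluster = c(0.6, 1.8, 4.0) * 1e-4,
                             censoring_max_days = 3650,
                             mutation = default_mutation_config(),
                             seed = 1L) {
  stopifnot(n_patients >= n_clusters, n_features >= 1, n_clusters >= 1)
  if (n_informative_features > n_features)
    stop("n_informative_features exceeds n_features", call. = FALSE)
  if (length(cluster_proportions) != n_clusters)
    stop("cluster_proportions must have one entry per cluster", call. = FALSE)
  if (any(cluster_proportions <= 0) ||
      abs(sum(cluster_proportions) - 1) > 1e-12)
    stop("cluster_proportions must be positive and sum to 1", call. = FALSE)
  if (length(hazard_per_cluster) != n_clusters ||
      any(hazard_per_cluster <= 0))
    stop("hazard_per_cluster must be strictly positive, one per cluster",
         call. = FALSE)
  if (scanner_effect_fraction < 0 || scanner_effect_fraction > 1)
    stop("scanner_effect_fraction must be in [0, 1]", call. = FALSE)
  cfg <- list(n_patients = as.integer(n_patients),
              n_features = as.integer(n_features),
              n_clusters = as.integer(n_clusters),
              cluster_proportions = cluster_proportions,
              n_informative_features = as.integer(n_informative_features),
              cluster_separation = cluster_separation,
              scanner_effect_fraction = scanner_effect_fraction,
              scanner_effect_scale = scanner_effect_scale,
              noise_sd = noise_sd,
              n_scanner_profiles = as.integer(n_scanner_profiles),
              hazard_per_cluster = hazard_per_cluster,
              censoring_max_days = censoring_max_days,
              mutation = mutation,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Default mutation-panel configuration
#'
#' A 20-gene panel of genes recurrently mutated in cervical cancer, with a
#' baseline per-gene mutation rate and cluster-enriched genes (chromatin/RAS
#' genes in cluster 2, PI3K/RTK genes in cluster 3).
#'
#' @param enrichment_odds Odds multiplier applied to enriched genes.
#' @return A list usable as the \code{mutation} field of [generator_config()].
#' @export
default_mutation_config <- function(enrichment_odds = 8) {
  list(genes = c("PIK3CA", "KMT2D", "KRAS", "ERBB2", "DDX3X", "CREBBP",
                 "TP53", "FBXW7", "EP300", "STK11", "NFE2L2", "ARID1A",
                 "PTEN", "SMAD4", "RB1", "MAPK1", "HLA-B", "NOTCH1",
                 "CASP8", "TGFBR2"),
       baseline_rate = 0.10,
       enriched = list("2" = c("KMT2D", "KRAS", "EP300"),
                       "3" = c("PIK3CA", "ERBB2", "DDX3X")),
       enrichment_odds = enrichment_odds)
}

# scanner profiles: balanced-but-shuffled categorical settings across
# profiles so no covariate is constant and no two are systematically aligned
.make_profiles <- function(n_profiles) {
  bal <- function(x) sample(rep(x, length.out = n_profiles))
  data.frame(
    pixel_spacing = stats::runif(n_profiles, 0.4, 0.9),
    slice_thickness = stats::runif(n_profiles, 3, 5),
    repetition_time = stats::runif(n_profiles, 3500, 6500),
    echo_time = stats::runif(n_profiles, 85, 115),
    flip_angle = bal(c(90, 120, 150)),
    n_averages = bal(1:4),
    field_strength = bal(c(1.5, 3.0)),
    echo_train_length = sample(15:25, n_profiles, replace = TRUE),
    phase_encoding_direction = bal(c("ROW", "COL")),
    highest_b_value = bal(c(800, 1000)),
    n_b_values = bal(2:4))
}

.generate_protocol <- function(n, n_profiles, deviation_rate = 0.15) {
  profiles <- .make_profiles(n_profiles)
  idx <- sample.int(n_profiles, n, replace = TRUE)
  p <- profiles[idx, , drop = FALSE]
  jitter <- function(x) x * exp(stats::rnorm(n, 0, 0.03))
  # protocol drift: per patient and per discrete field, occasional deviation
  # from the site profile (breaks the low-rank degeneracy a handful of
  # profiles would otherwise impose on the design)
  deviate <- function(x, values) {
    hit <- stats::runif(n) < deviation_rate
    x[hit] <- sample(values, sum(hit), replace = TRUE)
    x
  }
  pixel <- jitter(p$pixel_spacing)
  slice <- jitter(p$slice_thickness)
  data.frame(
    voxel_volume = slice * pixel^2,
    voxel_anisotropy = slice / pixel,
    repetition_time = jitter(p$repetition_time),
    echo_time = jitter(p$echo_time),
    flip_angle = deviate(p$flip_angle, c(90, 120, 150)),
    n_averages = deviate(p$n_averages, 1:4),
    field_strength = deviate(p$field_strength, c(1.5, 3.0)),
    echo_train_length = deviate(p$echo_train_length, 15:25),
    phase_encoding_direction = deviate(p$phase_encoding_direction,
                                       c("ROW", "COL")),
    highest_b_value = deviate(p$highest_b_value, c(800, 1000)),
    n_b_values = deviate(p$n_b_values, 2:4),
    row.names = NULL)
}

# standardized numeric covariate matrix used for planting scanner effects
.plant_design <- function(protocol) {
  x <- cbind(voxel_volume = protocol$voxel_volume,
             voxel_anisotropy = protocol$voxel_anisotropy,
             repetition_time = protocol$repetition_time,
             echo_time = protocol$echo_time,
             flip_angle = protocol$flip_angle,
             n_averages = protocol$n_averages,
             echo_train_length = protocol$echo_train_length,
             field_strength_3T = as.numeric(protocol$field_strength == 3.0),
             highest_b_value = protocol$highest_b_value,
             n_b_values = protocol$n_b_values)
  apply(x, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
}

# cluster-dependent clinical defaults, loosely patterned on a three-cluster
# cervical cancer cohort (younger intermediate-risk cluster, older high-risk
# cluster with advanced stage and large tumors); recycled for K != 3
.clinical_defaults <- function(K) {
  rec <- function(x) x[( seq_len(K) - 1 ) %% length(x) + 1]
  figo <- matrix(c(0.44, 0.25, 0.27, 0.04,
                   0.30, 0.22, 0.39, 0.09,
                   0.12, 0.21, 0.41, 0.26), nrow = 3, byrow = TRUE)
  hist <- matrix(c(0.73, 0.15, 0.12,
                   0.71, 0.26, 0.03,
                   0.94, 0.03, 0.03), nrow = 3, byrow = TRUE)
  list(age_median = rec(c(47, 40, 54)),
       age_sd = 12,
       figo_probs = figo[(seq_len(K) - 1) %% 3 + 1, , drop = FALSE],
       hist_probs = hist[(seq_len(K) - 1) %% 3 + 1, , drop = FALSE],
       diam_meanlog = rec(log(c(3.2, 4.4, 5.4))),
       diam_sdlog = 0.35)
}

#' Generate a synthetic cohort bundle
#'
#' Draws a full cohort from a [generator_config()]: feature value for patient
#' \eqn{i}, feature \eqn{j} is
#' \eqn{\mu_j(\mathrm{cluster}_i) + \sum_c \beta_{jc} x_{ic} + \epsilon_{ij}}
#' with \eqn{\epsilon \sim N(0, \mathrm{noise\_sd}^2)}; survival times are
#' exponential with the cluster's hazard, censored by an independent uniform
#' administrative time; mutation indicators are Bernoulli with odds-scaled
#' rates for cluster-enriched genes. Informative features are drawn uniformly
#' from the catalog excluding the tumor-volume feature, so the planted
#' cluster signal is orthogonal to volume by construction. Fully
#' deterministic given \code{config$seed}.
#'
#' @param config A [generator_config()].
#' @return A list of class \code{cohort_bundle} with elements
#'   \code{feature_matrix} (patients x features, catalog column names),
#'   \code{protocol} (acquisition-parameter table), \code{clinical}
#'   (DSS time/event, FIGO stage, age, histology, tumor diameter),
#'   \code{mutations} (binary patients x genes matrix or \code{NULL}) and
#'   \code{truth} (true labels, informative feature names, planted
#'   coefficients, planted log hazard ratios). All tables share the
#'   patient-ID row order.
#' @examples
#' b <- generate_cohort(generator_config(n_patients = 60, seed = 7))
#' dim(b$feature_matrix)
#' table(b$truth$true_cluster)
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_patients
  K <- config$n_clusters
  catalog <- build_catalog()
  if (config$n_features != nrow(catalog))
    stop("n_features must equal the catalog size (", nrow(catalog), ")",
         call. = FALSE)
  patient_id <- sprintf("P%03d", seq_len(n))

  # cluster labels: deterministic sizes from proportions (largest remainder),
  # then randomly ordered across patients
  sizes <- .apportion(n, config$cluster_proportions)
  labels <- sample(rep.int(seq_len(K), sizes))

  protocol <- .generate_protocol(n, config$n_scanner_profiles)
  rownames(protocol) <- patient_id

  # planted cluster means on informative features (volume excluded)
  p <- config$n_features
  eligible <- setdiff(catalog$name, volume_feature_name())
  informative <- sort(sample(eligible, config$n_informative_features))
  mu <- matrix(0, K, p, dimnames = list(NULL, catalog$name))
  for (f in informative) {
    lev <- (sample.int(K) - (K + 1) / 2) * config$cluster_separation *
      config$noise_sd
    mu[, f] <- lev
  }

  # planted scanner effects
  xp <- .plant_design(protocol)
  beta <- matrix(0, p, ncol(xp),
                 dimnames = list(catalog$name, colnames(xp)))
  n_affected <- round(config$scanner_effect_fraction * p)
  affected <- sort(sample.int(p, n_affected))
  if (n_affected > 0) {
    beta[affected, ] <- stats::rnorm(n_affected * ncol(xp),
                                     0, config$scanner_effect_scale)
    # b-value covariates only act on DWI/ADC-derived features
    dwi_adc <- catalog$series %in% c("high-b DWI", "ADC")
    beta[!dwi_adc, c("highest_b_value", "n_b_values")] <- 0
  }

  eps <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  feature_matrix <- mu[labels, , drop = FALSE] + xp %*% t(beta) + eps
  dimnames(feature_matrix) <- list(patient_id, catalog$name)

  clinical <- .generate_clinical(labels, config)
  rownames(clinical) <- patient_id

  mutations <- NULL
  if (!is.null(config$mutation)) {
    mutations <- .generate_mutations(labels, config$mutation)
    rownames(mutations) <- patient_id
  }

  truth <- list(true_cluster = labels,
                informative_features = informative,
                planted_coefficients = beta,
                planted_log_hazard_ratios =
                  log(config$hazard_per_cluster /
                        config$hazard_per_cluster[1]))

  bundle <- list(feature_matrix = feature_matrix, protocol = protocol,
                 clinical = clinical, mutations = mutations, truth = truth)
  class(bundle) <- "cohort_bundle"
  bundle
}

.generate_clinical <- function(labels, config) {
  n <- length(labels)
  K <- config$n_clusters
  def <- .clinical_defaults(K)
  age <- round(pmin(95, pmax(23, def$age_median[labels] +
                               stats::rnorm(n, 0, def$age_sd))))
  figo_levels <- c("IB", "II", "III", "IV")
  hist_levels <- c("SCC", "AC", "Other")
  figo <- vapply(labels, function(k)
    sample(figo_levels, 1, prob = def$figo_probs[k, ]), character(1))
  histology <- vapply(labels, function(k)
    sample(hist_levels, 1, prob = def$hist_probs[k, ]), character(1))
  diam <- stats::rlnorm(n, def$diam_meanlog[labels], def$diam_sdlog)

  event_time <- stats::rexp(n, rate = config$hazard_per_cluster[labels])
  censor_time <- stats::runif(n, 1, config$censoring_max_days)
  dss_time <- pmax(1, round(pmin(event_time, censor_time)))
  dss_event <- as.integer(event_time <= censor_time)

  data.frame(dss_time = dss_time, dss_event = dss_event,
             figo_stage = factor(figo, levels = figo_levels),
             age = age,
             histology = factor(histology, levels = hist_levels),
             max_tumor_diameter = diam)
}

.generate_mutations <- function(labels, mcfg) {
  n <- length(labels)
  genes <- mcfg$genes
  base_odds <- mcfg$baseline_rate / (1 - mcfg$baseline_rate)
  m <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  for (g in seq_along(genes)) {
    odds <- rep(base_odds, n)
    for (k in names(mcfg$enriched)) {
      if (genes[g] %in% mcfg$enriched[[k]]) {
        odds[labels == as.integer(k)] <- base_odds * mcfg$enrichment_odds
      }
    }
    rate <- odds / (1 + odds)
    m[, g] <- stats::rbinom(n, 1, rate)
  }
  m
}

# largest-remainder apportionment of n into proportional integer group sizes
.apportion <- function(n, prop) {
  raw <- n * prop
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a cohort bundle to a directory
#'
#' Writes \code{feature_matrix.csv}, \code{protocol.csv}, \code{clinical.csv},
#' optionally \code{mutations.csv} and \code{truth.json}; every table carries
#' a \code{patient_id} first column.
#'
#' @param bundle A \code{cohort_bundle}.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ids <- rownames(bundle$feature_matrix)
  wr <- function(tab, file) {
    df <- cbind(patient_id = ids, as.data.frame(tab, stringsAsFactors = FALSE))
    utils::write.csv(df, file.path(directory, file), row.names = FALSE)
  }
  wr(bundle$feature_matrix, "feature_matrix.csv")
  wr(bundle$protocol, "protocol.csv")
  wr(bundle$clinical, "clinical.csv")
  paths <- file.path(directory, c("feature_matrix.csv", "protocol.csv",
                                  "clinical.csv"))
  if (!is.null(bundle$mutations)) {
    wr(bundle$mutations, "mutations.csv")
    paths <- c(paths, file.path(directory, "mutations.csv"))
  }
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    json <- list(true_cluster = tr$true_cluster,
                 informative_features = tr$informative_features,
                 planted_log_hazard_ratios = tr$planted_log_hazard_ratios,
                 planted_coefficients = list(
                   features = rownames(tr$planted_coefficients),
                   covariates = colnames(tr$planted_coefficients),
                   values = lapply(seq_len(nrow(tr$planted_coefficients)),
                                   function(i)
                                     unname(tr$planted_coefficients[i, ]))))
    jsonlite::write_json(json, file.path(directory, "truth.json"),
                         auto_unbox = FALSE, digits = NA)
    paths <- c(paths, file.path(directory, "truth.json"))
  }
  invisible(paths)
}

.protocol_columns <- c("voxel_volume", "voxel_anisotropy", "repetition_time",
                       "echo_time", "flip_angle", "n_averages",
                       "field_strength", "echo_train_length",
                       "phase_encoding_direction", "highest_b_value",
                       "n_b_values")
.clinical_columns <- c("dss_time", "dss_event", "figo_stage", "age",
                       "histology", "max_tumor_diameter")

#' Read a cohort bundle from a directory
#'
#' Inverse of [write_bundle()]; validates the schema (required columns,
#' aligned patient IDs across tables) and reports offending column names.
#'
#' @param directory Directory containing the bundle files.
#' @return A \code{cohort_bundle}.
#' @export
read_bundle <- function(directory) {
  rd <- function(file, required = NULL) {
    path <- file.path(directory, file)
    if (!file.exists(path)) return(NULL)
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (!"patient_id" %in% colnames(df))
      stop(file, ": missing column patient_id", call. = FALSE)
    if (!is.null(required)) {
      miss <- setdiff(required, colnames(df))
      if (length(miss))
        stop(file, ": missing column(s) ", paste(miss, collapse = ", "),
             call. = FALSE)
    }
    df
  }
  fm <- rd("feature_matrix.csv")
  if (is.null(fm)) stop("feature_matrix.csv not found", call. = FALSE)
  ids <- fm$patient_id
  protocol <- rd("protocol.csv", .protocol_columns)
  clinical <- rd("clinical.csv", .clinical_columns)
  if (is.null(protocol) || is.null(clinical))
    stop("bundle requires protocol.csv and clinical.csv", call. = FALSE)
  for (nm in c("protocol.csv", "clinical.csv")) {
    tab <- if (nm == "protocol.csv") protocol else clinical
    if (!identical(tab$patient_id, ids))
      stop(nm, ": patient_id does not align with feature_matrix.csv",
           call. = FALSE)
  }
  mat <- as.matrix(fm[, -1, drop = FALSE])
  rownames(mat) <- ids
  proto <- protocol[, -1, drop = FALSE]
  rownames(proto) <- ids
  clin <- clinical[, -1, drop = FALSE]
  clin$figo_stage <- factor(clin$figo_stage,
                            levels = c("IB", "II", "III", "IV"))
  clin$histology <- factor(clin$histology, levels = c("SCC", "AC", "Other"))
  rownames(clin) <- ids

  mut <- rd("mutations.csv")
  if (!is.null(mut)) {
    if (!identical(mut$patient_id, ids))
      stop("mutations.csv: patient_id does not align with feature_matrix.csv",
           call. = FALSE)
    mm <- as.matrix(mut[, -1, drop = FALSE])
    rownames(mm) <- ids
    mut <- mm
  }

  truth <- NULL
  tpath <- file.path(directory, "truth.json")
  if (file.exists(tpath)) {
    tj <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    beta <- tj$planted_coefficients$values
    beta <- if (is.list(beta)) do.call(rbind, beta) else as.matrix(beta)
    dimnames(beta) <- list(tj$planted_coefficients$features,
                           tj$planted_coefficients$covariates)
    truth <- list(true_cluster = as.integer(tj$true_cluster),
                  informative_features = tj$informative_features,
                  planted_coefficients = beta,
                  planted_log_hazard_ratios = tj$planted_log_hazard_ratios)
  }

  bundle <- list(feature_matrix = mat, protocol = proto, clinical = clin,
                 mutations = mut, truth = truth)
  class(bundle) <- "cohort_bundle"
  bundle
}
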