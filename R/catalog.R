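# Feature catalog: the 293-feature schema used to label radiomic matrices.
#
# 14 shape descriptors are computed from the T2-weighted series only; the
# remaining six feature groups (first-order + five texture families, 93
# features) are computed once per intensity series (T2WI, high b-value DWI,
# ADC), giving 14 + 3 x 93 = 293 features. Per-group membership follows the
# default feature classes of the standard extraction tooling.

.shape_features <- c(
  "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "Maximum2DDiameterSlice",
  "Maximum3DDiameter", "MeshVolume", "MinorAxisLength", "Sphericity",
  "SurfaceArea", "SurfaceVolumeRatio", "VoxelVolume")

.firstorder_features <- c(
  "10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
  "Kurtosis", "Maximum", "Mean", "MeanAbsoluteDeviation", "Median", "Minimum",
  "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
  "TotalEnergy", "Uniformity", "Variance")

.glcm_features <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "MCC", "SumAverage", "SumEntropy", "SumSquares")

.gldm_features <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

.glrlm_features <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

.glszm_features <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

.ngtdm_features <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                     "Strength")

.series_levels <- c("shape(T2WI)", "T2WI", "high-b DWI", "ADC")
.group_levels <- c("shape", "firstorder", "glcm", "gldm", "glrlm", "glszm",
                   "ngtdm")
# column-name prefix per intensity series
.series_prefix <- c("T2WI" = "T2WI", "high-b DWI" = "DWI", "ADC" = "ADC")

#' Build the 293-feature radiomic catalog
#'
#' Constructs the schema of the radiomic feature set: 14 tumor shape features
#' (derived from the T2-weighted series only, including tumor volume) plus 93
#' intensity/texture features for each of the three MR series (T2WI, high
#' b-value DWI, ADC map), 293 features in total. Feature names follow the
#' convention \code{<series>_<group>_<feature>}, e.g.
#' \code{"ADC_ngtdm_Busyness"}; the tumor-volume feature is
#' \code{"T2WI_shape_MeshVolume"}.
#'
#' @return A data frame of class \code{feature_catalog} with columns
#'   \code{name}, \code{series} (one of \code{"shape(T2WI)"}, \code{"T2WI"},
#'   \code{"high-b DWI"}, \code{"ADC"}) and \code{group} (one of the seven
#'   feature groups), ordered shape-first then per series by group.
#' @examples
#' cat <- build_catalog()
#' nrow(cat)                       # 293
#' sum(cat$group == "shape")      # 14
#' @export
build_catalog <- function() {
  shape <- data.frame(
    name = paste0("T2WI_shape_", .shape_features),
    series = "shape(T2WI)", group = "shape",
    stringsAsFactors = FALSE)
  groups <- list(firstorder = .firstorder_features, glcm = .glcm_features,
                 gldm = .gldm_features, glrlm = .glrlm_features,
                 glszm = .glszm_features, ngtdm = .ngtdm_features)
  per_series <- lapply(c("T2WI", "high-b DWI", "ADC"), function(s) {
    do.call(rbind, lapply(names(groups), function(g) {
      data.frame(
        name = paste0(.series_prefix[[s]], "_", g, "_", groups[[g]]),
        series = s, group = g, stringsAsFactors = FALSE)
    }))
  })
  cat <- rbind(shape, do.call(rbind, per_series))
  rownames(cat) <- NULL
  class(cat) <- c("feature_catalog", "data.frame")
  cat
}

#' Name of the tumor-volume feature
#'
#' @return The catalog name of the shape feature recording tumor volume.
#' @export
volume_feature_name <- function() "T2WI_shape_MeshVolume"

.catalog_lookup <- function(name, catalog = build_catalog()) {
  i <- match(name, catalog$name)
  if (anyNA(i)) {
    stop("unknown feature name(s): ",
         paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  }
  catalog[i, , drop = FALSE]
}

#' Series and group attribution of a feature
#'
#' @param name Feature name(s) as in the catalog.
#' @param catalog A catalog from [build_catalog()].
#' @return Character vector of series (`series_of`) or group (`group_of`).
#' @export
series_of <- function(name, catalog = build_catalog()) {
  .catalog_lookup(name, catalog)$series
}

#' @rdname series_of
#' @export
group_of <- function(name, catalog = build_catalog()) {
  .catalog_lookup(name, catalog)$group
}

#' Validate a feature matrix against the catalog
#'
#' Checks that the column names of a patient-by-feature matrix are exactly the
#' catalog feature names (order-insensitive) and reports any discrepancy.
#'
#' @param matrix A matrix or data frame with named feature columns.
#' @param catalog A catalog from [build_catalog()].
#' @return A list with elements \code{pass} (logical), \code{n_expected},
#'   \code{n_observed}, \code{missing} (catalog names absent from the matrix)
#'   and \code{extra} (matrix columns not in the catalog).
#' @export
validate_matrix <- function(matrix, catalog = build_catalog()) {
  cols <- colnames(matrix)
  if (is.null(cols)) stop("feature matrix must have column names",
                          call. = FALSE)
  missing <- setdiff(catalog$name, cols)
  extra <- setdiff(cols, catalog$name)
  list(pass = length(missing) == 0 && length(extra) == 0,
       n_expected = nrow(catalog), n_observed = length(cols),
       missing = missing, extra = extra)
}

#' Export the catalog as TSV
#'
#' @param catalog A catalog from [build_catalog()].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_catalog <- function(catalog = build_catalog(), path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
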