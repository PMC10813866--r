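.radiomics_classes <- list(
  shape = c("Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
            "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
            "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
            "MinorAxisLength", "Sphericity", "SurfaceArea",
            "SurfaceVolumeRatio", "VoxelVolume"),
  firstorder = c("10Percentile", "90Percentile", "Energy", "Entropy",
                 "InterquartileRange", "Kurtosis", "Maximum",
                 "MeanAbsoluteDeviation", "Mean", "Median", "Minimum",
                 "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                 "Skewness", "TotalEnergy", "Uniformity", "Variance"),
  glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
           "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
           "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
           "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
           "SumAverage", "SumEntropy", "SumSquares"),
  glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelRunEmphasis",
            "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
            "RunEntropy", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "RunVariance", "ShortRunEmphasis",
            "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
  glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
            "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
            "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
            "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
            "ZoneVariance"),
  gldm = c("DependenceEntropy", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "DependenceVariance",
           "GrayLevelNonUniformity", "GrayLevelVariance",
           "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
           "LargeDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
           "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis"),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
)

.wavelet_bands <- c("LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH", "LLL")

#' Canonical CT radiomics feature-name schema
#'
#' Enumerates the standard 851-name schema of a default IBSI-compliant CT
#' extraction with wavelet filtering enabled: on the original image, 14
#' shape (3D) features plus 18 first-order and the five texture families
#' (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5; 93 intensity/texture
#' features in all), and the same 93 on each of the 8 wavelet sub-bands
#' (LLH...LLL). Shape features describe mask geometry and are computed on
#' the original image only. Names follow the
#' `{imagetype}_{class}_{feature}` convention, e.g.
#' `wavelet.HLL_glszm_GrayLevelVariance`. The order is deterministic.
#'
#' @return character vector of 851 feature names, with a `schema`
#'   data.frame (columns `name`, `image_type`, `class`, `feature`)
#'   attached as attribute "table".
#' @export
enumerate_radiomics_schema <- function() {
  rows <- list()
  add <- function(image_type, class) {
    feats <- .radiomics_classes[[class]]
    data.frame(name = paste(image_type, class, feats, sep = "_"),
               image_type = image_type, class = class, feature = feats,
               stringsAsFactors = FALSE)
  }
  rows[[1]] <- add("original", "shape")
  for (cl in c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm"))
    rows[[length(rows) + 1L]] <- add("original", cl)
  for (band in .wavelet_bands)
    for (cl in c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm"))
      rows[[length(rows) + 1L]] <- add(paste0("wavelet.", band), cl)
  tab <- do.call(rbind, rows)
  structure(tab$name, table = tab)
}

#' Read a radiomics feature table from CSV
#'
#' Parses a patients-by-features CSV keyed by a `patient_id` column,
#' coercing feature columns to numeric. Non-numeric cells and duplicated
#' patient ids are hard errors; the table is returned together with a
#' schema-conformance report (advisory: synthetic cohorts use generic
#' feature names and proceed with a warning).
#'
#' @param path CSV file path.
#' @param schema schema names to validate against (default the canonical
#'   851-name schema).
#' @return list with `table` (data.frame, `patient_id` + numeric columns)
#'   and `report` (see [validate_schema()]).
#' @export
read_radiomics_table <- function(path, schema = enumerate_radiomics_schema()) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("radiomics table file is missing or empty: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(tab))
    stop("radiomics table lacks a patient_id column")
  tab$patient_id <- as.character(tab$patient_id)
  if (anyDuplicated(tab$patient_id))
    stop("duplicate patient_id values: ",
         paste(unique(tab$patient_id[duplicated(tab$patient_id)]),
               collapse = ", "))
  feat_cols <- setdiff(names(tab), "patient_id")
  bad <- character(0)
  for (cn in feat_cols) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    nn <- which(is.na(v) & !is.na(tab[[cn]]) & tab[[cn]] != "")
    if (length(nn))
      bad <- c(bad, sprintf("%s[row %d]='%s'", cn, nn, tab[[cn]][nn]))
    tab[[cn]] <- v
  }
  if (length(bad))
    stop("non-numeric cells in radiomics table: ",
         paste(utils::head(bad, 10), collapse = "; "))
  report <- validate_schema(tab, schema)
  if (report$coverage == 0)
    warning("no radiomics column matches the canonical schema; ",
            "proceeding with generic feature names")
  list(table = tab, report = report)
}

#' Validate a feature table against a schema
#'
#' Pure set comparison of the table's feature column names against a
#' schema; never mutates the data.
#'
#' @param table data.frame with a `patient_id` column.
#' @param schema character vector of canonical names.
#' @return list with `missing` (schema names absent from the table),
#'   `extra` (table columns outside the schema), and `coverage`
#'   (fraction of schema names present).
#' @export
validate_schema <- function(table, schema = enumerate_radiomics_schema()) {
  cols <- setdiff(names(table), "patient_id")
  missing <- setdiff(schema, cols)
  extra <- setdiff(cols, schema)
  if (length(extra))
    warning("columns outside the canonical schema: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) sprintf(" (and %d more)", length(extra) - 5)
            else "")
  list(missing = missing, extra = extra,
       coverage = 1 - length(missing) / length(schema))
}
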