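## Canonical feature registry: the single source of truth for feature names,
## family membership and column order of every feature table produced by the
## package. 80 features: 4 FOS + 24 GLCM + 16 GLSZM + 16 GLRLM + 15 GLDM +
## 5 NGTDM.

.FOS_FEATURES <- c("Mean", "Variance", "Skewness", "Kurtosis")

.GLCM_FEATURES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "InverseDifference", "InverseDifferenceMoment",
  "InverseDifferenceMomentNormalized", "InverseDifferenceNormalized",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximalCorrelationCoefficient", "MaximumProbability", "SumAverage",
  "SumEntropy", "SumSquares", "InformationalMeasureCorrelation1",
  "InformationalMeasureCorrelation2")

.GLSZM_FEATURES <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

.GLRLM_FEATURES <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

## 14 canonical dependence features plus GrayLevelNonUniformityNormalized,
## giving the 15-feature GLDM panel used by this pipeline.
.GLDM_FEATURES <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "DependenceNonUniformity", "DependenceNonUniformityNormalized",
  "GrayLevelVariance", "DependenceVariance", "DependenceEntropy",
  "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LargeDependenceHighGrayLevelEmphasis")

.NGTDM_FEATURES <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                     "Strength")

#' Canonical texture-feature registry
#'
#' Returns the 80-feature registry used throughout the package: feature
#' names, family tags and canonical column order. Every feature table,
#' selector and report orders features exactly as listed here, and all
#' tie-breaking in the selectors falls back to this order.
#'
#' @return A \code{data.frame} with columns \code{name} (e.g.
#'   \code{"GLCM_Contrast"}), \code{family} (one of FOS, GLCM, GLSZM, GLRLM,
#'   GLDM, NGTDM) and \code{feature} (the family-local feature name), with
#'   exactly 80 rows.
#' @examples
#' reg <- featureRegistry()
#' nrow(reg)            # 80
#' table(reg$family)
#' @export
featureRegistry <- function() {
  fam <- list(FOS = .FOS_FEATURES, GLCM = .GLCM_FEATURES,
              GLSZM = .GLSZM_FEATURES, GLRLM = .GLRLM_FEATURES,
              GLDM = .GLDM_FEATURES, NGTDM = .NGTDM_FEATURES)
  data.frame(
    name = unlist(lapply(names(fam), function(f) paste(f, fam[[f]], sep = "_")),
                  use.names = FALSE),
    family = rep(names(fam), lengths(fam)),
    feature = unlist(fam, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Feature names in canonical order
#'
#' @param family Optional family tag to restrict to (e.g. \code{"GLCM"}).
#' @return Character vector of canonical \code{FAMILY_Feature} names.
#' @export
featureNames <- function(family = NULL) {
  reg <- featureRegistry()
  if (!is.null(family)) {
    family <- match.arg(family, unique(reg$family))
    reg <- reg[reg$family == family, , drop = FALSE]
  }
  reg$name
}

# Order a set of registry names canonically, dropping duplicates.
orderByRegistry <- function(names) {
  reg <- featureNames()
  bad <- setdiff(names, reg)
  if (length(bad))
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  reg[reg %in% names]
}
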