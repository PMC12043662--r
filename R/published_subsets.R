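## Feature panels reported by a published application of this pipeline to
## SHG-imaged airway collagen (control vs. remodeled), one panel per
## refinement method. They are shipped so that panel-level operations —
## notably pooling to the 33-feature union — can be reproduced without the
## original (unshared) image dataset.

.AIRWAY_PANELS <- list(
  anova_f = c(
    "GLCM_Correlation", "GLCM_MaximalCorrelationCoefficient",
    "NGTDM_Busyness",
    "GLSZM_LargeAreaEmphasis", "GLSZM_LargeAreaLowGrayLevelEmphasis",
    "GLSZM_ZoneVariance",
    "GLRLM_ShortRunLowGrayLevelEmphasis",
    "GLRLM_GrayLevelNonUniformityNormalized",
    "GLRLM_GrayLevelNonUniformity", "GLRLM_RunEntropy"),
  permutation = c(
    "GLCM_JointEntropy", "GLCM_DifferenceEntropy",
    "GLCM_InverseDifferenceNormalized",
    "GLSZM_SmallAreaEmphasis", "GLSZM_SizeZoneNonUniformityNormalized",
    "GLRLM_RunVariance", "GLRLM_LongRunLowGrayLevelEmphasis",
    "GLRLM_HighGrayLevelRunEmphasis",
    "GLDM_LowGrayLevelEmphasis"),
  rfe = c(
    "GLCM_Correlation",
    "GLSZM_LargeAreaEmphasis", "GLSZM_LargeAreaLowGrayLevelEmphasis",
    "GLSZM_ZonePercentage",
    "GLRLM_ShortRunLowGrayLevelEmphasis",
    "GLRLM_GrayLevelNonUniformityNormalized", "GLRLM_RunEntropy"),
  cov = c(
    "GLCM_Autocorrelation", "GLCM_ClusterProminence", "GLCM_ClusterShade",
    "GLCM_ClusterTendency",
    "NGTDM_Coarseness", "NGTDM_Busyness",
    "GLSZM_LargeAreaEmphasis", "GLSZM_HighGrayLevelZoneEmphasis",
    "GLSZM_SmallAreaHighGrayLevelEmphasis", "GLSZM_GrayLevelVariance",
    "GLSZM_ZoneVariance",
    "GLRLM_ShortRunHighGrayLevelEmphasis", "GLRLM_GrayLevelVariance",
    "GLRLM_RunVariance",
    "GLDM_HighGrayLevelEmphasis",
    "GLDM_SmallDependenceHighGrayLevelEmphasis", "GLDM_GrayLevelVariance"))

#' Published airway-collagen feature panels
#'
#' The four refined feature panels (10 ANOVA F-test, 9 permutation
#' importance, 7 RFE and 17 coefficient-of-variation features) reported for
#' SHG-imaged airway collagen classification. Pooling the four panels with
#' \code{\link{poolSubsets}} yields the 33-feature union panel.
#'
#' @return A named list of four \code{\linkS4class{FeatureSubset}} objects
#'   (\code{anova_f}, \code{permutation}, \code{rfe}, \code{cov}).
#' @examples
#' panels <- airwayPanels()
#' lengths(lapply(panels, subsetFeatures))      # 10, 9, 7, 17
#' length(poolSubsets(panels))                  # 33
#' @export
airwayPanels <- function() {
  out <- lapply(names(.AIRWAY_PANELS), function(m)
    featureSubset(.AIRWAY_PANELS[[m]], method = m))
  names(out) <- names(.AIRWAY_PANELS)
  out
}
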