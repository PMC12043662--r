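#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

## ---------------------------------------------------------------- FiberParams

#' Parameters of the synthetic fibrillar phantom generator
#'
#' \code{FiberParams} holds the full parameterization of one synthetic
#' SHG-like image: raster size, fiber count and geometry (length, thickness),
#' the orientation distribution (von Mises, with concentration
#' \code{orientationKappa}; 0 means isotropic), fiber brightness, optical
#' blur and additive background noise. Identical parameters and seed always
#' yield a byte-identical image.
#'
#' @slot imageHeightPx,imageWidthPx Raster dimensions in pixels.
#' @slot nFibers Number of fiber segments rendered.
#' @slot lengthMeanPx,lengthSdPx Mean and SD of fiber length (pixels);
#'   lengths are drawn from a normal distribution truncated at 1 px.
#' @slot thicknessPx Fiber thickness (pixels) of the anti-aliased segment.
#' @slot orientationMeanRad Mean orientation in radians, in [0, pi).
#' @slot orientationKappa von Mises concentration; 0 gives uniform
#'   orientations, large values give strongly aligned fibers.
#' @slot fiberIntensity Peak fiber gray value in (0, 255].
#' @slot backgroundNoiseSd SD of additive Gaussian background noise.
#' @slot blurSigmaPx Gaussian blur sigma (pixels) applied before noise.
#' @slot seed Integer RNG seed.
#' @seealso \code{\link{fiberParams}}, \code{\link{generateImage}}
#' @export
setClass("FiberParams", representation(
  imageHeightPx = "integer", imageWidthPx = "integer", nFibers = "integer",
  lengthMeanPx = "numeric", lengthSdPx = "numeric", thicknessPx = "numeric",
  orientationMeanRad = "numeric", orientationKappa = "numeric",
  fiberIntensity = "numeric", backgroundNoiseSd = "numeric",
  blurSigmaPx = "numeric", seed = "integer"))

setValidity("FiberParams", function(object) {
  msg <- character()
  if (object@imageHeightPx < 2L || object@imageWidthPx < 2L)
    msg <- c(msg, "image dimensions must be >= 2 px")
  if (object@nFibers < 0L) msg <- c(msg, "nFibers must be >= 0")
  if (object@lengthMeanPx <= 0) msg <- c(msg, "lengthMeanPx must be positive")
  if (object@lengthSdPx < 0) msg <- c(msg, "lengthSdPx must be >= 0")
  if (object@thicknessPx <= 0) msg <- c(msg, "thicknessPx must be positive")
  if (object@orientationMeanRad < 0 || object@orientationMeanRad >= pi)
    msg <- c(msg, "orientationMeanRad must lie in [0, pi)")
  if (object@orientationKappa < 0) msg <- c(msg, "orientationKappa must be >= 0")
  if (object@fiberIntensity <= 0 || object@fiberIntensity > 255)
    msg <- c(msg, "fiberIntensity must lie in (0, 255]")
  if (object@backgroundNoiseSd < 0) msg <- c(msg, "backgroundNoiseSd must be >= 0")
  if (object@blurSigmaPx < 0) msg <- c(msg, "blurSigmaPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct fiber-phantom parameters
#'
#' @param imageHeightPx,imageWidthPx Raster size in pixels (default 450).
#' @param nFibers Number of fibers.
#' @param lengthMeanPx,lengthSdPx Fiber length distribution (normal,
#'   truncated at 1 px).
#' @param thicknessPx Fiber thickness in pixels.
#' @param orientationMeanRad Mean fiber orientation, radians in [0, pi).
#' @param orientationKappa von Mises concentration (0 = isotropic).
#' @param fiberIntensity Peak fiber gray value in (0, 255].
#' @param backgroundNoiseSd SD of additive Gaussian background noise.
#' @param blurSigmaPx Gaussian blur sigma in pixels.
#' @param seed RNG seed.
#' @return A validated \code{\linkS4class{FiberParams}} object.
#' @examples
#' p <- fiberParams(nFibers = 10, seed = 1)
#' img <- generateImage(p)
#' @export
fiberParams <- function(imageHeightPx = 450L, imageWidthPx = 450L,
                        nFibers = 60L, lengthMeanPx = 150, lengthSdPx = 40,
                        thicknessPx = 3, orientationMeanRad = pi / 3,
                        orientationKappa = 6, fiberIntensity = 180,
                        backgroundNoiseSd = 6, blurSigmaPx = 1.2,
                        seed = 1L) {
  new("FiberParams",
      imageHeightPx = as.integer(imageHeightPx),
      imageWidthPx = as.integer(imageWidthPx),
      nFibers = as.integer(nFibers),
      lengthMeanPx = as.numeric(lengthMeanPx),
      lengthSdPx = as.numeric(lengthSdPx),
      thicknessPx = as.numeric(thicknessPx),
      orientationMeanRad = as.numeric(orientationMeanRad),
      orientationKappa = as.numeric(orientationKappa),
      fiberIntensity = as.numeric(fiberIntensity),
      backgroundNoiseSd = as.numeric(backgroundNoiseSd),
      blurSigmaPx = as.numeric(blurSigmaPx),
      seed = as.integer(seed))
}

setMethod("show", "FiberParams", function(object) {
  cat("FiberParams:", object@imageHeightPx, "x", object@imageWidthPx, "px,",
      object@nFibers, "fibers\n")
  cat(sprintf("  length %.4g +/- %.4g px, thickness %.3g px\n",
              object@lengthMeanPx, object@lengthSdPx, object@thicknessPx))
  cat(sprintf("  orientation mean %.3g rad, kappa %.3g\n",
              object@orientationMeanRad, object@orientationKappa))
  cat(sprintf("  intensity %.4g, noise sd %.3g, blur %.3g px, seed %d\n",
              object@fiberIntensity, object@backgroundNoiseSd,
              object@blurSigmaPx, object@seed))
})

## ------------------------------------------------------------ QuantizedImage

#' Gray-level quantized image
#'
#' Integer level map produced by \code{\link{quantizeImage}}: each pixel of
#' an 8-bit image is assigned to one of \code{nLevels} equal-width bins over
#' [0, 256). Levels are stored 0-based; all texture-matrix builders consume
#' this representation.
#'
#' @slot levels Integer matrix of levels in [0, nLevels).
#' @slot nLevels Number of gray levels (2..256).
#' @slot binEdges Numeric vector of bin edges over [0, 256].
#' @export
setClass("QuantizedImage", representation(
  levels = "matrix", nLevels = "integer", binEdges = "numeric"))

setValidity("QuantizedImage", function(object) {
  if (object@nLevels < 2L || object@nLevels > 256L)
    return("nLevels must be in [2, 256]")
  if (any(object@levels < 0L) || any(object@levels >= object@nLevels))
    return("levels must lie in [0, nLevels)")
  TRUE
})

setMethod("show", "QuantizedImage", function(object) {
  cat("QuantizedImage:", nrow(object@levels), "x", ncol(object@levels),
      "px,", object@nLevels, "gray levels\n")
})

#' @rdname QuantizedImage-class
#' @param x A \code{QuantizedImage}.
#' @return \code{levelMap} returns the 0-based integer level matrix;
#'   \code{nLevels} the number of levels.
#' @export
levelMap <- function(x) x@levels

#' @rdname QuantizedImage-class
#' @export
nLevels <- function(x) x@nLevels

## ------------------------------------------------------------- TextureMatrix

#' Gray-level texture matrix
#'
#' A family-tagged count or probability table produced by one of the matrix
#' builders (\code{\link{glcm}}, \code{\link{glrlm}}, \code{\link{glszm}},
#' \code{\link{gldm}}, \code{\link{ngtdm}}). For NGTDM the \code{table} slot
#' holds the per-level triples (n_i, p_i, s_i) as a 3-column matrix instead
#' of a 2-D histogram.
#'
#' @slot family One of GLCM, GLSZM, GLRLM, GLDM, NGTDM.
#' @slot direction Direction in degrees (0, 45, 90, 135) for directional
#'   families; \code{NA} for the direction-free ones.
#' @slot table Numeric matrix of counts/probabilities (levels in rows).
#' @slot normalization \code{"counts"} or \code{"probability"}.
#' @slot degenerate \code{TRUE} when the image admitted no valid pairs/runs
#'   for this direction (e.g. a 1-pixel-wide image scanned vertically).
#' @slot nPixels Number of pixels in the source image.
#' @export
setClass("TextureMatrix", representation(
  family = "character", direction = "numeric", table = "matrix",
  normalization = "character", degenerate = "logical", nPixels = "integer"))

setValidity("TextureMatrix", function(object) {
  if (!object@family %in% c("GLCM", "GLSZM", "GLRLM", "GLDM", "NGTDM"))
    return("unknown family")
  if (!object@normalization %in% c("counts", "probability"))
    return("normalization must be 'counts' or 'probability'")
  if (any(object@table < 0)) return("table entries must be non-negative")
  if (object@normalization == "probability" && !object@degenerate &&
      abs(sum(object@table) - 1) > 1e-9)
    return("probability table must sum to 1")
  TRUE
})

setMethod("show", "TextureMatrix", function(object) {
  cat(sprintf("TextureMatrix [%s]%s: %d x %d (%s)%s\n", object@family,
              if (!is.na(object@direction))
                sprintf(" %g deg", object@direction) else "",
              nrow(object@table), ncol(object@table), object@normalization,
              if (object@degenerate) " DEGENERATE" else ""))
})

#' @rdname TextureMatrix-class
#' @param x A \code{TextureMatrix}.
#' @return \code{matrixTable} returns the underlying numeric table;
#'   \code{matrixFamily} the family tag; \code{isDegenerate} the degeneracy
#'   flag.
#' @export
matrixTable <- function(x) x@table

#' @rdname TextureMatrix-class
#' @export
matrixFamily <- function(x) x@family

#' @rdname TextureMatrix-class
#' @export
isDegenerate <- function(x) x@degenerate

## --------------------------------------------------------- TextureExperiment

#' Container for extracted texture features
#'
#' \code{TextureExperiment} extends
#' \code{\linkS4class{SummarizedExperiment}}: the \code{"features"} assay is
#' an 80 x n matrix (features in canonical registry order x images), and
#' \code{colData} carries at least a two-level \code{label} factor plus any
#' per-image provenance (source file, generator seed). All cleaning,
#' selection and classification functions operate on this container.
#'
#' @seealso \code{\link{extractFeatureTable}}, \code{\link{cleanFeatures}}
#' @export
setClass("TextureExperiment", contains = "SummarizedExperiment")

setValidity("TextureExperiment", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  if (!"label" %in% colnames(colData(object)))
    return("colData must contain a 'label' column")
  reg <- featureNames()
  rn <- rownames(object)
  if (!all(rn %in% reg))
    return("rownames must be canonical registry feature names")
  if (is.unsorted(match(rn, reg)))
    return("features must appear in canonical registry order")
  TRUE
})

#' Build a TextureExperiment from a feature matrix and labels
#'
#' @param features Numeric matrix, features x images, rownames drawn from
#'   \code{\link{featureNames}} (any subset, canonical order enforced).
#' @param labels Per-image class labels (coerced to factor).
#' @param colData Optional extra per-image columns (data.frame).
#' @return A \code{\linkS4class{TextureExperiment}}.
#' @export
textureExperiment <- function(features, labels, colData = NULL) {
  features <- as.matrix(features)
  ord <- order(match(rownames(features), featureNames()))
  features <- features[ord, , drop = FALSE]
  cd <- DataFrame(label = factor(labels))
  if (!is.null(colData)) cd <- cbind(cd, DataFrame(colData))
  reg <- featureRegistry()
  rd <- DataFrame(family = reg$family[match(rownames(features), reg$name)])
  new("TextureExperiment",
      SummarizedExperiment(assays = list(features = features),
                           colData = cd, rowData = rd))
}

#' @rdname TextureExperiment-class
#' @param x A \code{TextureExperiment}.
#' @return \code{featureMatrix} returns the features x images numeric
#'   matrix; \code{imageLabels} the per-image factor of class labels.
#' @export
featureMatrix <- function(x) assay(x, "features")

#' @rdname TextureExperiment-class
#' @export
imageLabels <- function(x) colData(x)$label

setMethod("show", "TextureExperiment", function(object) {
  callNextMethod()
  cat("labels:", paste(sprintf("%s=%d", levels(imageLabels(object)),
                               table(imageLabels(object))), collapse = ", "),
      "\n")
})

## -------------------------------------------------------------- FeatureSubset

#' A refined feature subset
#'
#' The output of one feature-refinement strategy: an ordered list of
#' canonical feature names with the method tag, optional per-feature scores
#' and the parameters used. Subsets from several methods can be merged with
#' \code{\link{poolSubsets}}.
#'
#' @slot method One of \code{anova_f}, \code{rfe}, \code{permutation},
#'   \code{cov}, \code{pooled}, \code{manual}.
#' @slot features Canonical feature names, in registry order.
#' @slot scores Optional named per-feature scores (may be empty).
#' @slot params Named list of method parameters used.
#' @export
setClass("FeatureSubset", representation(
  method = "character", features = "character", scores = "numeric",
  params = "list"))

setValidity("FeatureSubset", function(object) {
  if (!object@method %in% c("anova_f", "rfe", "permutation", "cov", "pooled",
                            "manual"))
    return("unknown method tag")
  if (length(object@features) == 0L) return("subset must be non-empty")
  if (anyDuplicated(object@features)) return("duplicate feature names")
  if (!all(object@features %in% featureNames()))
    return("features must be canonical registry names")
  TRUE
})

#' Construct a FeatureSubset
#'
#' @param features Canonical feature names (reordered to registry order).
#' @param method Method tag (default \code{"manual"}).
#' @param scores Optional per-feature scores, named by feature.
#' @param params Named list of method parameters.
#' @return A \code{\linkS4class{FeatureSubset}}.
#' @export
featureSubset <- function(features, method = "manual", scores = numeric(),
                          params = list()) {
  feats <- orderByRegistry(unique(features))
  if (length(scores)) scores <- scores[feats]
  new("FeatureSubset", method = method, features = feats,
      scores = scores, params = params)
}

#' @rdname FeatureSubset-class
#' @param x A \code{FeatureSubset}.
#' @return \code{subsetFeatures} returns the character vector of feature
#'   names; \code{subsetMethod} the method tag.
#' @export
subsetFeatures <- function(x) x@features

#' @rdname FeatureSubset-class
#' @export
subsetMethod <- function(x) x@method

setMethod("show", "FeatureSubset", function(object) {
  cat(sprintf("FeatureSubset [%s]: %d features\n", object@method,
              length(object@features)))
  cat(" ", paste(utils::head(object@features, 8), collapse = ", "),
      if (length(object@features) > 8) "...", "\n")
})

#' @describeIn FeatureSubset-class Number of features in the subset.
#' @export
setMethod("length", "FeatureSubset", function(x) length(x@features))

## ------------------------------------------------------------ EvaluationReport

#' Classifier evaluation report
#'
#' Metrics produced by \code{\link{evaluateRepeatedKFold}} or
#' \code{\link{evaluateHoldout}}: per-fold accuracies (k-fold protocol),
#' per-class precision/recall/F1, macro-averaged ROC-AUC and the confusion
#' matrix, together with the subset and seeds used.
#'
#' @slot protocol \code{"repeated_kfold"} or \code{"holdout"}.
#' @slot foldAccuracy Per-fold accuracies (k-fold) or the single holdout
#'   accuracy.
#' @slot accuracyMean,accuracySd Summary of \code{foldAccuracy}.
#' @slot classMetrics data.frame with per-class precision, recall, F1.
#' @slot aucMacro Macro-averaged ROC-AUC (mean over folds for k-fold).
#' @slot aucSd SD of per-fold AUCs (0 for holdout).
#' @slot confusion Confusion matrix (rows = truth, cols = predicted).
#' @slot subset Features used.
#' @slot seed Seed used for splitting.
#' @export
setClass("EvaluationReport", representation(
  protocol = "character", foldAccuracy = "numeric", accuracyMean = "numeric",
  accuracySd = "numeric", classMetrics = "data.frame", aucMacro = "numeric",
  aucSd = "numeric", confusion = "matrix", subset = "character",
  seed = "integer"))

setValidity("EvaluationReport", function(object) {
  if (!object@protocol %in% c("repeated_kfold", "holdout"))
    return("unknown protocol")
  r <- c(object@foldAccuracy, object@accuracyMean, object@aucMacro)
  if (any(r < 0 | r > 1)) return("rates must lie in [0, 1]")
  TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s], %d feature(s)\n", object@protocol,
              length(object@subset)))
  cat(sprintf("  accuracy %.3f +/- %.3f (%d fold(s))\n", object@accuracyMean,
              object@accuracySd, length(object@foldAccuracy)))
  cat(sprintf("  macro ROC-AUC %.3f +/- %.3f\n", object@aucMacro, object@aucSd))
  if (nrow(object@classMetrics)) {
    cat("  per-class metrics:\n")
    print(object@classMetrics, digits = 3)
  }
})

#' @rdname EvaluationReport-class
#' @param x An \code{EvaluationReport}.
#' @return \code{reportAccuracy} returns the mean accuracy;
#'   \code{reportAuc} the macro ROC-AUC; \code{reportConfusion} the
#'   confusion matrix; \code{reportClassMetrics} the per-class data.frame.
#' @export
reportAccuracy <- function(x) x@accuracyMean

#' @rdname EvaluationReport-class
#' @export
reportAuc <- function(x) x@aucMacro

#' @rdname EvaluationReport-class
#' @export
reportConfusion <- function(x) x@confusion

#' @rdname EvaluationReport-class
#' @export
reportClassMetrics <- function(x) x@classMetrics
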