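## Full-panel feature extraction: first-order statistics from the raw 8-bit
## intensities, then the five matrix families on the quantized image. GLCM
## and GLRLM features are computed per direction (0, 45, 90, 135 degrees)
## and arithmetically averaged at the feature level; GLSZM, GLDM and NGTDM
## are direction-free.

.DIRECTIONS <- c(0, 45, 90, 135)

#' Extract the 80-feature texture panel from one image
#'
#' @param image 8-bit integer matrix (values in [0, 255]).
#' @param nLevels Gray levels for quantization (default 64).
#' @param distance Inter-pixel distance for GLCM and GLDM neighborhoods
#'   (default 1).
#' @param alpha GLDM level-similarity tolerance (default 0).
#' @param connectivity GLSZM zone connectivity, 8 (default) or 4.
#' @return Named numeric vector of exactly 80 finite values in canonical
#'   registry order. Directions admitting no pixel pairs (degenerate) are
#'   excluded from the directional average with a warning.
#' @examples
#' v <- extractFeatures(generateImage(fiberParams(imageHeightPx = 64L,
#'   imageWidthPx = 64L, nFibers = 10L, lengthMeanPx = 20, seed = 1)))
#' length(v)   # 80
#' @export
extractFeatures <- function(image, nLevels = 64L, distance = 1L,
                            alpha = 0L, connectivity = 8L) {
  q <- quantizeImage(image, nLevels)
  out <- stats::setNames(numeric(80), featureNames())
  out[names(computeFOS(image))] <- computeFOS(image)

  dirAverage <- function(mats, family) {
    ok <- !vapply(mats, isDegenerate, logical(1))
    if (!all(ok))
      warning(sprintf("%s: %d degenerate direction(s) excluded from average",
                      family, sum(!ok)), call. = FALSE)
    if (!any(ok)) ok[] <- TRUE   # all degenerate: fall back to the limits
    rowMeans(vapply(mats[ok], featuresFromMatrix,
                    numeric(length(featureNames(family)))))
  }
  gl <- dirAverage(lapply(.DIRECTIONS, function(d)
    glcm(q, d, distance = distance)), "GLCM")
  rl <- dirAverage(lapply(.DIRECTIONS, function(d) glrlm(q, d)), "GLRLM")
  out[names(gl)] <- gl
  out[names(rl)] <- rl
  zones <- .glszmZones(q, connectivity = connectivity)
  sz <- .rlszTriplets(zones[, "level"] + 1L, zones[, "size"],
                      zones[, "count"], length(levelMap(q)), "GLSZM")
  dm <- featuresFromMatrix(gldm(q, alpha = alpha, distance = distance))
  nt <- featuresFromMatrix(ngtdm(q, distance = distance))
  out[names(sz)] <- sz
  out[names(dm)] <- dm
  out[names(nt)] <- nt
  stopifnot(all(is.finite(out)))
  out
}

#' Extract a feature table from a set of images
#'
#' Runs \code{\link{extractFeatures}} on every image and assembles the
#' results into a \code{\linkS4class{TextureExperiment}} (80 features x
#' n images, plus labels).
#'
#' @param images List of 8-bit integer matrices.
#' @param labels Per-image class labels (length matching \code{images}).
#' @param ... Passed on to \code{\link{extractFeatures}}.
#' @param verbose Print a progress line every 50 images.
#' @return A \code{\linkS4class{TextureExperiment}}.
#' @export
extractFeatureTable <- function(images, labels, ..., verbose = FALSE) {
  stopifnot(length(images) == length(labels))
  feats <- matrix(NA_real_, 80L, length(images),
                  dimnames = list(featureNames(),
                                  names(images) %||%
                                    sprintf("img%03d", seq_along(images))))
  for (i in seq_along(images)) {
    feats[, i] <- extractFeatures(images[[i]], ...)
    if (verbose && i %% 50L == 0L)
      message("extracted ", i, "/", length(images), " images")
  }
  textureExperiment(feats, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feature table as CSV
#'
#' The on-disk layout is one row per image: \code{image_id}, \code{label},
#' then the feature columns in canonical registry order.
#'
#' @param x A \code{\linkS4class{TextureExperiment}}.
#' @param path CSV path.
#' @return \code{writeFeatureCSV} returns \code{path} invisibly;
#'   \code{readFeatureCSV} returns a \code{TextureExperiment}.
#' @export
writeFeatureCSV <- function(x, path) {
  df <- data.frame(image_id = colnames(x),
                   label = as.character(imageLabels(x)),
                   t(featureMatrix(x)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  feats <- intersect(names(df), featureNames())
  mat <- t(as.matrix(df[, feats, drop = FALSE]))
  colnames(mat) <- df$image_id
  textureExperiment(mat, df$label)
}
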