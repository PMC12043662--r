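## Synthetic SHG-like fibrillar phantom generator. Two phenotypes are
## caricatured: "control" images contain long, coherent, preferentially
## aligned bright fibers; "remodeled" images contain many short, fragmented
## segments with isotropic orientations. The generator exists so that the
## full texture pipeline can be exercised and validated without donor
## imaging data; it makes no claim of optical realism.

# Sample from a von Mises distribution on [0, 2*pi) by the Best-Fisher
# rejection algorithm; kappa = 0 falls back to the circular uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# Anti-aliased coverage patch of one thick segment: coverage =
# clamp(thickness/2 + 0.5 - distance to the segment), evaluated only over
# the segment's bounding box. The caller max-blends the patch into the
# canvas in place (fibers occlude rather than add). Rows index y, origin
# top-left.
segmentPatch <- function(h, w, x0, y0, x1, y1, thickness, intensity) {
  half <- thickness / 2 + 0.5
  lox <- max(1L, as.integer(floor(min(x0, x1) - half)))
  hix <- min(w, as.integer(ceiling(max(x0, x1) + half)))
  loy <- max(1L, as.integer(floor(min(y0, y1) - half)))
  hiy <- min(h, as.integer(ceiling(max(y0, y1) + half)))
  if (lox > hix || loy > hiy) return(NULL)
  rx <- lox:hix; ry <- loy:hiy
  px <- matrix(rx, nrow = length(ry), ncol = length(rx), byrow = TRUE)
  py <- matrix(ry, nrow = length(ry), ncol = length(rx))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 < 1e-12) {
    d <- sqrt((px - x0)^2 + (py - y0)^2)
  } else {
    t <- pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
    d <- sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
  }
  list(ry = ry, rx = rx,
       cov = intensity * pmin(1, pmax(0, thickness / 2 + 0.5 - d)))
}

#' Generate one synthetic fibrillar image
#'
#' Renders \code{nFibers} anti-aliased straight segments with lengths drawn
#' from a truncated normal and orientations from a von Mises distribution,
#' applies Gaussian blur, adds background noise, and clips/rounds to an
#' 8-bit raster. The result is fully determined by \code{params} (including
#' its \code{seed} slot).
#'
#' @param params A \code{\linkS4class{FiberParams}} object.
#' @return Integer matrix (rows x cols) with values in [0, 255] and
#'   attribute \code{bitDepth = 8}.
#' @examples
#' img <- generateImage(fiberParams(nFibers = 5, seed = 7))
#' range(img)
#' @export
generateImage <- function(params) {
  validObject(params)
  h <- params@imageHeightPx; w <- params@imageWidthPx
  withSeed(params@seed, {
    canvas <- matrix(0, h, w)
    n <- params@nFibers
    if (n > 0L) {
      cx <- runif(n, 1, w)
      cy <- runif(n, 1, h)
      len <- pmax(1, rnorm(n, params@lengthMeanPx, params@lengthSdPx))
      theta <- rvonmises(n, params@orientationMeanRad, params@orientationKappa) %% pi
      for (i in seq_len(n)) {
        dx <- cos(theta[i]) * len[i] / 2
        dy <- sin(theta[i]) * len[i] / 2
        p <- segmentPatch(h, w, cx[i] - dx, cy[i] - dy,
                          cx[i] + dx, cy[i] + dy,
                          params@thicknessPx, params@fiberIntensity)
        if (!is.null(p))
          canvas[p$ry, p$rx] <- pmax(canvas[p$ry, p$rx], p$cov)
      }
    }
    if (params@blurSigmaPx > 0)
      canvas <- gaussianBlur(canvas, params@blurSigmaPx)
    if (params@backgroundNoiseSd > 0)
      canvas <- canvas + matrix(rnorm(h * w, 0, params@backgroundNoiseSd), h, w)
    out <- matrix(as.integer(pmin(255, pmax(0, round(canvas)))), h, w)
    attr(out, "bitDepth") <- 8L
    out
  })
}

# Separable Gaussian blur with reflected edges (EBImage's gblur pads with
# zeros, which darkens fibers near borders; a small hand-rolled separable
# kernel keeps edge statistics sensible).
gaussianBlur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(x, r) {
    top <- x[rev(seq_len(min(r, nrow(x)))), , drop = FALSE]
    bot <- x[nrow(x) + 1 - rev(seq_len(min(r, nrow(x)))), , drop = FALSE]
    while (nrow(top) < r) top <- rbind(top[1, , drop = FALSE], top)
    while (nrow(bot) < r) bot <- rbind(bot, bot[nrow(bot), , drop = FALSE])
    rbind(top, x, bot)
  }
  convCols <- function(x) {
    xp <- pad(x, r)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(convCols(t(convCols(m))))
}

#' Presets for the two phantom phenotypes
#'
#' \code{"control"}: few long, thick, strongly aligned fibers (coherent
#' arrangement). \code{"remodeled"}: many short segments with isotropic
#' orientations (fragmented structure). \code{"null"} is an alias for the
#' control preset, used to build no-effect datasets where both classes share
#' identical parameters.
#'
#' @param phenotype \code{"control"}, \code{"remodeled"} or \code{"null"}.
#' @param seed Seed stored in the returned parameters.
#' @param imageSizePx Square raster side (default 450).
#' @return A \code{\linkS4class{FiberParams}} object.
#' @export
fiberPreset <- function(phenotype = c("control", "remodeled", "null"),
                        seed = 1L, imageSizePx = 450L) {
  phenotype <- match.arg(phenotype)
  scale <- imageSizePx / 450
  switch(phenotype,
    control = fiberParams(imageHeightPx = imageSizePx,
                          imageWidthPx = imageSizePx,
                          nFibers = as.integer(round(45 * scale^2)),
                          lengthMeanPx = 200 * scale, lengthSdPx = 50 * scale,
                          thicknessPx = 3.5, orientationMeanRad = pi / 3,
                          orientationKappa = 8, fiberIntensity = 180,
                          backgroundNoiseSd = 6, blurSigmaPx = 1.2,
                          seed = seed),
    remodeled = fiberParams(imageHeightPx = imageSizePx,
                            imageWidthPx = imageSizePx,
                            nFibers = as.integer(round(260 * scale^2)),
                            lengthMeanPx = 22 * scale, lengthSdPx = 8 * scale,
                            thicknessPx = 2.8, orientationMeanRad = pi / 3,
                            orientationKappa = 0, fiberIntensity = 180,
                            backgroundNoiseSd = 6, blurSigmaPx = 1.2,
                            seed = seed),
    null = fiberPreset("control", seed = seed, imageSizePx = imageSizePx))
}

#' Generate a labeled two-class phantom dataset
#'
#' Produces \code{2 * nPerClass} images with exactly balanced labels.
#' Per-image seeds are derived deterministically from the master seed and
#' the image index, so any image can be regenerated in isolation and the
#' whole dataset is reproducible bit-for-bit.
#'
#' @param control,remodeled \code{\linkS4class{FiberParams}} for the two
#'   classes (their \code{seed} slots are overridden per image).
#' @param nPerClass Images per class (>= 1).
#' @param seed Master seed for the dataset.
#' @param dir Optional directory; when given, each image is written as an
#'   8-bit grayscale TIFF plus a \code{manifest.csv}
#'   (filename,label,seed).
#' @return A list with elements \code{images} (list of integer matrices),
#'   \code{labels} (factor control/remodeled) and \code{manifest}
#'   (data.frame: filename, label, seed).
#' @examples
#' ds <- generateDataset(fiberPreset("control", imageSizePx = 64L),
#'                       fiberPreset("remodeled", imageSizePx = 64L),
#'                       nPerClass = 2, seed = 1)
#' table(ds$labels)
#' @export
generateDataset <- function(control, remodeled, nPerClass, seed = 1L,
                            dir = NULL) {
  if (!is.numeric(nPerClass) || nPerClass < 1)
    stop("'nPerClass' must be >= 1", call. = FALSE)
  nPerClass <- as.integer(nPerClass)
  paramsFor <- list(control = control, remodeled = remodeled)
  labels <- rep(c("control", "remodeled"), each = nPerClass)
  n <- length(labels)
  images <- vector("list", n)
  seeds <- integer(n)
  for (i in seq_len(n)) {
    p <- paramsFor[[labels[i]]]
    seeds[i] <- deriveSeed(seed, i)
    p@seed <- seeds[i]
    images[[i]] <- generateImage(p)
  }
  manifest <- data.frame(
    filename = sprintf("%s_%03d.tif", labels, seq_len(n)),
    label = labels, seed = seeds, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n))
      tiff::writeTIFF(images[[i]] / 255, file.path(dir, manifest$filename[i]),
                      bits.per.sample = 8L)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, labels = factor(labels), manifest = manifest)
}
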