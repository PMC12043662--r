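## Builders for the five gray-level texture matrices. All operate on a
## QuantizedImage (0-based levels) and return a TextureMatrix whose rows
## index gray level 1..nLevels. Directions follow the usual image-analysis
## convention with a top-left origin and (row, col) offsets:
##   0 deg -> (0, 1), 45 deg -> (-1, 1), 90 deg -> (-1, 0),
##   135 deg -> (-1, -1).

.DIRECTION_OFFSETS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                           `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Quantize an 8-bit image to a fixed number of gray levels
#'
#' Equal-width binning of [0, 256) into \code{nLevels} bins:
#' \code{level = floor(v * nLevels / 256)}. With \code{nLevels = 256} the
#' mapping is the identity.
#'
#' @param image Integer matrix with values in [0, 255].
#' @param nLevels Number of gray levels, in [2, 256] (default 64).
#' @return A \code{\linkS4class{QuantizedImage}}.
#' @examples
#' q <- quantizeImage(matrix(as.integer(c(0, 128, 255, 64)), 2, 2),
#'                    nLevels = 4)
#' levelMap(q)
#' @export
quantizeImage <- function(image, nLevels = 64L) {
  .assertScalarNumber(nLevels, "nLevels", 2, 256)
  nLevels <- as.integer(nLevels)
  if (any(image < 0L) || any(image > 255L))
    stop("image values must lie in [0, 255]", call. = FALSE)
  lv <- matrix(as.integer((as.double(image) * nLevels) %/% 256),
               nrow(image), ncol(image))
  new("QuantizedImage", levels = lv, nLevels = nLevels,
      binEdges = seq(0, 256, length.out = nLevels + 1L))
}

# Extract the two level vectors (a at the origin pixel, b at the offset
# pixel) for all in-image pixel pairs under offset (dr, dc).
.offsetPairs <- function(lv, dr, dc) {
  h <- nrow(lv); w <- ncol(lv)
  rlo <- max(1L, 1L - dr); rhi <- min(h, h - dr)
  clo <- max(1L, 1L - dc); chi <- min(w, w - dc)
  if (rlo > rhi || clo > chi) return(list(a = integer(), b = integer()))
  r0 <- rlo:rhi; c0 <- clo:chi
  list(a = as.vector(lv[r0, c0, drop = FALSE]),
       b = as.vector(lv[r0 + dr, c0 + dc, drop = FALSE]))
}

#' Gray-level co-occurrence matrix (GLCM)
#'
#' Symmetric co-occurrence counts at the given direction and inter-pixel
#' distance: each ordered pair is counted in both directions, so the raw
#' count total is twice the number of valid in-image offset pairs. With
#' \code{normalize = TRUE} (default) the table is scaled to probabilities.
#'
#' @param q A \code{\linkS4class{QuantizedImage}}.
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @param distance Inter-pixel distance in pixels (default 1).
#' @param normalize Return probabilities (default) or raw counts.
#' @return A \code{\linkS4class{TextureMatrix}} with an nLevels x nLevels
#'   table; flagged degenerate when the image admits no pair at this offset.
#' @export
glcm <- function(q, direction = 0, distance = 1L, normalize = TRUE) {
  dir <- as.character(direction)
  if (!dir %in% names(.DIRECTION_OFFSETS))
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE)
  off <- .DIRECTION_OFFSETS[[dir]] * as.integer(distance)
  nL <- q@nLevels
  pr <- .offsetPairs(q@levels, off[1L], off[2L])
  counts <- matrix(0, nL, nL)
  if (length(pr$a)) {
    tab <- tabulate(pr$a * nL + pr$b + 1L, nbins = nL * nL)
    counts <- matrix(tab, nL, nL, byrow = TRUE)   # rows = a, cols = b
    counts <- counts + t(counts)                  # symmetric accumulation
  }
  degenerate <- sum(counts) == 0
  if (normalize && !degenerate) counts <- counts / sum(counts)
  new("TextureMatrix", family = "GLCM", direction = as.numeric(direction),
      table = counts,
      normalization = if (normalize && !degenerate) "probability" else "counts",
      degenerate = degenerate, nPixels = length(q@levels))
}

# Maximal runs of equal levels along one direction, as a two-column matrix
# (level, run length). Rows/columns/diagonals are separated by a sentinel
# so a single rle pass covers the whole image.
.runs <- function(lv, direction) {
  h <- nrow(lv); w <- ncol(lv)
  seqs <- switch(as.character(direction),
    `0`   = as.vector(rbind(t(lv), -1L)),
    `90`  = as.vector(rbind(lv, -1L)),
    `45`  = {
      key <- as.vector(row(lv) + col(lv))
      unlist(lapply(split(as.vector(lv), key), function(x) c(x, -1L)),
             use.names = FALSE)
    },
    `135` = {
      key <- as.vector(row(lv) - col(lv))
      unlist(lapply(split(as.vector(lv), key), function(x) c(x, -1L)),
             use.names = FALSE)
    },
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
  r <- rle(seqs)
  keep <- r$values >= 0L
  cbind(level = r$values[keep], length = r$lengths[keep])
}

#' Gray-level run length matrix (GLRLM)
#'
#' Entry (g, r) counts the maximal runs of gray level g with length exactly
#' r along the chosen direction.
#'
#' @inheritParams glcm
#' @return A \code{\linkS4class{TextureMatrix}} of raw counts with
#'   nLevels rows and max-run-length columns.
#' @export
glrlm <- function(q, direction = 0) {
  runs <- .runs(q@levels, direction)
  nL <- q@nLevels
  maxR <- if (nrow(runs)) max(runs[, "length"]) else 1L
  tab <- tabulate((runs[, "length"] - 1L) * nL + runs[, "level"] + 1L,
                  nbins = nL * maxR)
  new("TextureMatrix", family = "GLRLM", direction = as.numeric(direction),
      table = matrix(tab, nL, maxR), normalization = "counts",
      degenerate = nrow(runs) == 0L, nPixels = length(q@levels))
}

# Zone list of a quantized image as triplets (level, size, count); the
# sparse form used both to materialize the dense GLSZM and to compute its
# features without scanning a levels-by-maxsize dense table. Zone
# extraction itself is a compiled union-find pass (src/zones.cpp).
.glszmZones <- function(q, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  zones <- .zoneTable(q@levels, as.integer(connectivity))
  key <- as.double(zones[, "level"]) * (length(q@levels) + 1) +
    zones[, "size"]
  agg <- rle(sort(key))
  np1 <- length(q@levels) + 1
  cbind(level = as.integer(agg$values %/% np1),
        size = as.integer(agg$values %% np1),
        count = agg$lengths)
}

#' Gray-level size zone matrix (GLSZM)
#'
#' Entry (g, s) counts the connected zones of gray level g comprising
#' exactly s pixels, under 8- (default) or 4-connectivity. Direction-free.
#'
#' @inheritParams glcm
#' @param connectivity 8 (default) or 4.
#' @return A \code{\linkS4class{TextureMatrix}} of raw counts with nLevels
#'   rows and max-zone-size columns.
#' @export
glszm <- function(q, connectivity = 8L) {
  zones <- .glszmZones(q, connectivity)
  nL <- q@nLevels
  maxS <- max(zones[, "size"])
  tab <- matrix(0, nL, maxS)
  tab[cbind(zones[, "level"] + 1L, zones[, "size"])] <- zones[, "count"]
  new("TextureMatrix", family = "GLSZM", direction = NA_real_,
      table = tab, normalization = "counts",
      degenerate = FALSE, nPixels = length(q@levels))
}

# Per-pixel count of neighbors within Chebyshev distance `distance` whose
# level differs from the center by at most alpha.
.dependenceCounts <- function(lv, alpha, distance) {
  h <- nrow(lv); w <- ncol(lv)
  dep <- matrix(0L, h, w)
  for (dr in -distance:distance) for (dc in -distance:distance) {
    if (dr == 0L && dc == 0L) next
    rlo <- max(1L, 1L - dr); rhi <- min(h, h - dr)
    clo <- max(1L, 1L - dc); chi <- min(w, w - dc)
    if (rlo > rhi || clo > chi) next
    r0 <- rlo:rhi; c0 <- clo:chi
    ok <- abs(lv[r0, c0, drop = FALSE] -
                lv[r0 + dr, c0 + dc, drop = FALSE]) <= alpha
    dep[r0, c0] <- dep[r0, c0] + ok
  }
  dep
}

#' Gray-level dependence matrix (GLDM)
#'
#' For each pixel of level g, its dependence is the number of neighbors
#' within Chebyshev distance \code{distance} whose level differs from g by
#' at most \code{alpha}. Entry (g, j) counts pixels with dependence j - 1
#' (columns start at dependence 0). Direction-free.
#'
#' @inheritParams glcm
#' @param alpha Level-similarity tolerance (default 0, exact match).
#' @param distance Chebyshev neighborhood radius (default 1).
#' @return A \code{\linkS4class{TextureMatrix}} of raw counts.
#' @export
gldm <- function(q, alpha = 0L, distance = 1L) {
  if (alpha < 0L) stop("alpha must be >= 0", call. = FALSE)
  lv <- q@levels; nL <- q@nLevels
  dep <- .dependenceCounts(lv, as.integer(alpha), as.integer(distance))
  maxD <- max(dep) + 1L
  tab <- tabulate(dep * nL + lv + 1L, nbins = nL * maxD)
  new("TextureMatrix", family = "GLDM", direction = NA_real_,
      table = matrix(tab, nL, maxD), normalization = "counts",
      degenerate = FALSE, nPixels = length(lv))
}

#' Neighboring gray tone difference matrix (NGTDM)
#'
#' Per gray level i: n_i, the pixel count; p_i = n_i / N; and
#' s_i, the summed absolute difference between i and the mean level of each
#' pixel's valid in-image neighbors (8-neighborhood at distance 1).
#' Direction-free.
#'
#' @inheritParams gldm
#' @return A \code{\linkS4class{TextureMatrix}} whose table has one row per
#'   gray level and columns \code{n}, \code{p}, \code{s}.
#' @export
ngtdm <- function(q, distance = 1L) {
  lv <- q@levels; nL <- q@nLevels
  h <- nrow(lv); w <- ncol(lv)
  d <- as.integer(distance)
  nbSum <- matrix(0, h, w); nbCnt <- matrix(0L, h, w)
  for (dr in -d:d) for (dc in -d:d) {
    if (dr == 0L && dc == 0L) next
    rlo <- max(1L, 1L - dr); rhi <- min(h, h - dr)
    clo <- max(1L, 1L - dc); chi <- min(w, w - dc)
    if (rlo > rhi || clo > chi) next
    r0 <- rlo:rhi; c0 <- clo:chi
    nbSum[r0, c0] <- nbSum[r0, c0] + lv[r0 + dr, c0 + dc, drop = FALSE]
    nbCnt[r0, c0] <- nbCnt[r0, c0] + 1L
  }
  diffs <- abs(as.vector(lv) - as.vector(nbSum) / as.vector(nbCnt))
  n_i <- tabulate(as.vector(lv) + 1L, nbins = nL)
  rs <- rowsum(diffs, group = as.vector(lv))
  s_i <- numeric(nL)
  s_i[as.integer(rownames(rs)) + 1L] <- as.vector(rs)
  tab <- cbind(n = n_i, p = n_i / length(lv), s = s_i)
  new("TextureMatrix", family = "NGTDM", direction = NA_real_,
      table = tab, normalization = "counts", degenerate = FALSE,
      nPixels = length(lv))
}
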