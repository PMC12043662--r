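## Image preprocessing: grayscale TIFF loading, 16-to-8-bit conversion and
## the low-signal intensity filter applied before texture extraction.

#' Read a single-channel grayscale TIFF
#'
#' Reads an 8- or 16-bit single-page grayscale TIFF into an integer matrix.
#' RGB/multi-channel and multi-page files are rejected.
#'
#' @param path Path to the TIFF file.
#' @return Integer matrix with attribute \code{bitDepth} (8 or 16).
#' @export
readGrayTIFF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) != 1L)
    stop("multi-page TIFF not supported (", length(pages), " pages): ",
         path, call. = FALSE)
  img <- pages[[1L]]
  if (length(dim(img)) == 3L)
    stop("multi-channel TIFF not supported (", dim(img)[3L],
         " channels): ", path, call. = FALSE)
  bps <- attr(img, "bits.per.sample")
  ## some writers omit bits.per.sample; fall back on the value range
  bits <- if (!is.null(bps)) as.integer(bps)
          else if (max(img) > 255L) 16L else 8L
  if (!bits %in% c(8L, 16L))
    stop("unsupported bit depth: ", bits, call. = FALSE)
  attributes(img) <- list(dim = dim(img))
  storage.mode(img) <- "integer"
  attr(img, "bitDepth") <- bits
  img
}

#' Convert a 16-bit image to 8-bit
#'
#' Two conversion modes are provided. \code{fixed_shift} (default) divides
#' by 256 and truncates, preserving cross-image intensity comparability —
#' the property the downstream low-signal filter relies on. \code{minmax}
#' linearly maps the observed [min, max] to [0, 255] with round-half-even;
#' a constant image maps to 0. An 8-bit input is returned unchanged with a
#' warning.
#'
#' @param image Integer matrix with attribute \code{bitDepth}.
#' @param mode \code{"fixed_shift"} or \code{"minmax"}.
#' @return Integer matrix with \code{bitDepth = 8}.
#' @export
to8bit <- function(image, mode = c("fixed_shift", "minmax")) {
  mode <- match.arg(mode)
  bits <- attr(image, "bitDepth")
  if (!is.null(bits) && bits == 8L) {
    warning("input is already 8-bit; returning unchanged")
    return(image)
  }
  out <- if (mode == "fixed_shift") {
    image %/% 256L
  } else {
    lo <- min(image); hi <- max(image)
    if (hi == lo) matrix(0L, nrow(image), ncol(image))
    else matrix(as.integer(round((as.double(image) - lo) / (hi - lo) * 255)),
                nrow(image), ncol(image))
  }
  storage.mode(out) <- "integer"
  attr(out, "bitDepth") <- 8L
  out
}

#' Filter out low-signal images
#'
#' An image is rejected when its mean pixel intensity falls strictly below
#' \code{threshold} (default 5 on the 8-bit scale); an image exactly at the
#' threshold is kept. The filter is idempotent and order-independent.
#'
#' @param images List of 8-bit integer matrices (optionally named).
#' @param threshold Mean-intensity threshold (default 5).
#' @return A data.frame (one row per image) with columns \code{id},
#'   \code{meanIntensity} and \code{kept}.
#' @examples
#' imgs <- list(dark = matrix(0L, 4, 4), bright = matrix(50L, 4, 4))
#' filterLowSignal(imgs)
#' @export
filterLowSignal <- function(images, threshold = 5) {
  if (length(images) == 0L)
    return(data.frame(id = character(), meanIntensity = numeric(),
                      kept = logical(), stringsAsFactors = FALSE))
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  means <- vapply(images, function(m) mean(as.double(m)), numeric(1))
  data.frame(id = ids, meanIntensity = unname(means),
             kept = unname(means >= threshold), stringsAsFactors = FALSE)
}
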