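## Per-feature outlier cleaning: Tukey/IQR fences with median substitution.
## Values outside the fences are replaced by the feature's median computed
## over all original values (including the outliers). When the IQR
## collapses to zero the fences coincide and replacement is skipped, so
## near-constant features are never overwritten wholesale.

#' Tukey fences of a numeric vector
#'
#' Quartiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7); fences are \code{Q1 - k*IQR} and
#' \code{Q3 + k*IQR}.
#'
#' @param values Numeric vector with at least 4 values.
#' @param k Fence multiplier (default 1.5).
#' @return Named numeric vector \code{c(lower, upper)} with attributes
#'   \code{q1} and \code{q3}.
#' @examples
#' iqrFences(c(1, 2, 3, 4, 100))   # lower -1, upper 7
#' @export
iqrFences <- function(values, k = 1.5) {
  if (length(values) < 4L)
    stop("at least 4 values are required for stable quartiles",
         call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  structure(c(lower = q[1L] - k * iqr, upper = q[2L] + k * iqr),
            q1 = q[1L], q3 = q[2L])
}

#' Clean a feature table by IQR outlier substitution
#'
#' Each feature (row) is treated independently: values outside its Tukey
#' fences are replaced by the feature's median over all original values.
#' Row/column counts and label alignment are preserved. Feature medians are
#' preserved by the substitution (exactly so for odd sample counts; for
#' even counts the median may drift within the central pair of order
#' statistics).
#'
#' @param x A \code{\linkS4class{TextureExperiment}}.
#' @param k Fence multiplier (default 1.5).
#' @return A list with \code{cleaned} (a \code{TextureExperiment}) and
#'   \code{report} (a data.frame with per-feature \code{q1}, \code{q3},
#'   \code{lower}, \code{upper}, \code{median}, \code{nReplaced}).
#' @export
cleanFeatures <- function(x, k = 1.5) {
  mat <- featureMatrix(x)
  if (!is.numeric(mat) || any(!is.finite(mat)))
    stop("feature table must be fully numeric and finite", call. = FALSE)
  rep_n <- integer(nrow(mat))
  info <- matrix(NA_real_, nrow(mat), 5L,
                 dimnames = list(rownames(mat),
                                 c("q1", "q3", "lower", "upper", "median")))
  for (r in seq_len(nrow(mat))) {
    v <- mat[r, ]
    f <- iqrFences(v, k)
    med <- stats::median(v)
    info[r, ] <- c(attr(f, "q1"), attr(f, "q3"), f["lower"], f["upper"], med)
    if (f["upper"] > f["lower"]) {          # IQR = 0 guard
      out <- v < f["lower"] | v > f["upper"]
      rep_n[r] <- sum(out)
      if (any(out)) mat[r, out] <- med
    }
  }
  cleaned <- x
  SummarizedExperiment::assay(cleaned, "features") <- mat
  report <- data.frame(feature = rownames(mat), info,
                       nReplaced = rep_n, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(cleaned = cleaned, report = report)
}
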