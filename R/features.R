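## Feature calculators for the five matrix families plus first-order
## statistics. Gray levels enter the formulas as 1-based values (row index
## of the matrix), run lengths / zone sizes as their natural values, and
## GLDM dependence as (dependence + 1) so that inverse-square weights are
## always defined. Entropies are base 2 with the 0*log(0) = 0 convention.
##
## Degenerate-case conventions (all centralized here, never NaN):
##   * constant image / zero-variance marginals: GLCM Correlation = 1 and
##     MaximalCorrelationCoefficient = 1;
##   * NGTDM Coarseness capped at 1e6 when sum(p_i * s_i) = 0; Busyness,
##     Complexity, Strength and Contrast fall back to 0 when their
##     denominators vanish (single occupied level or zero neighborhood
##     differences);
##   * FOS skewness and kurtosis are 0 for a zero-variance image;
##   * an all-zero (degenerate) directional matrix yields the constant-image
##     values; extract-level averaging excludes such directions instead.

#' First-order statistics of an 8-bit image
#'
#' Mean, population variance, skewness and kurtosis of the raw intensity
#' histogram. Skewness and kurtosis are defined as 0 for a constant image.
#'
#' @param image Integer matrix with values in [0, 255].
#' @return Named numeric vector \code{FOS_Mean}, \code{FOS_Variance},
#'   \code{FOS_Skewness}, \code{FOS_Kurtosis}.
#' @export
computeFOS <- function(image) {
  v <- as.double(image)
  if (!length(v)) stop("empty image", call. = FALSE)
  m <- mean(v)
  cv <- v - m
  s2 <- mean(cv^2)
  if (s2 > 0) {
    skew <- mean(cv^3) / s2^1.5
    kurt <- mean(cv^4) / s2^2
  } else skew <- kurt <- 0
  c(FOS_Mean = m, FOS_Variance = s2, FOS_Skewness = skew,
    FOS_Kurtosis = kurt)
}

.glcmFeatures <- function(P) {
  nG <- nrow(P)
  tot <- sum(P)
  out <- stats::setNames(numeric(24), featureNames("GLCM"))
  if (tot == 0) {           # degenerate direction: constant-image limits
    out[] <- 0
    out["GLCM_Correlation"] <- 1
    out["GLCM_MaximalCorrelationCoefficient"] <- 1
    out["GLCM_MaximumProbability"] <- 1
    out["GLCM_JointEnergy"] <- 1
    return(out)
  }
  P <- P / tot
  i <- matrix(seq_len(nG), nG, nG)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(nG) * px); muy <- sum(seq_len(nG) * py)
  sx2 <- sum((seq_len(nG) - mux)^2 * px)
  sy2 <- sum((seq_len(nG) - muy)^2 * py)
  ## diagonal and cross-diagonal marginals
  dsum <- rowsum(as.vector(P), group = as.vector(i + j))          # i+j
  kplus <- as.numeric(rownames(dsum)); pplus <- as.vector(dsum)
  ddif <- rowsum(as.vector(P), group = as.vector(abs(i - j)))     # |i-j|
  kdif <- as.numeric(rownames(ddif)); pdif <- as.vector(ddif)

  out["GLCM_Autocorrelation"] <- sum(i * j * P)
  ct <- (i + j - mux - muy)
  out["GLCM_ClusterProminence"] <- sum(ct^4 * P)
  out["GLCM_ClusterShade"] <- sum(ct^3 * P)
  out["GLCM_ClusterTendency"] <- sum(ct^2 * P)
  out["GLCM_Contrast"] <- sum((i - j)^2 * P)
  out["GLCM_Correlation"] <- if (sx2 > 0 && sy2 > 0)
    (sum(i * j * P) - mux * muy) / sqrt(sx2 * sy2) else 1
  da <- sum(kdif * pdif)
  out["GLCM_DifferenceAverage"] <- da
  out["GLCM_DifferenceEntropy"] <- -sum(xlog2x(pdif))
  out["GLCM_DifferenceVariance"] <- sum((kdif - da)^2 * pdif)
  out["GLCM_InverseDifference"] <- sum(P / (1 + abs(i - j)))
  out["GLCM_InverseDifferenceMoment"] <- sum(P / (1 + (i - j)^2))
  out["GLCM_InverseDifferenceMomentNormalized"] <-
    sum(P / (1 + (i - j)^2 / nG^2))
  out["GLCM_InverseDifferenceNormalized"] <- sum(P / (1 + abs(i - j) / nG))
  off <- i != j
  out["GLCM_InverseVariance"] <- sum(P[off] / (i[off] - j[off])^2)
  out["GLCM_JointAverage"] <- mux
  out["GLCM_JointEnergy"] <- sum(P^2)
  hxy <- -sum(xlog2x(P))
  out["GLCM_JointEntropy"] <- hxy
  out["GLCM_MaximalCorrelationCoefficient"] <- .glcmMCC(P, px, py)
  out["GLCM_MaximumProbability"] <- max(P)
  out["GLCM_SumAverage"] <- sum(kplus * pplus)
  out["GLCM_SumEntropy"] <- -sum(xlog2x(pplus))
  out["GLCM_SumSquares"] <- sx2
  hx <- -sum(xlog2x(px)); hy <- -sum(xlog2x(py))
  pxy <- outer(px, py)
  pos <- P > 0
  hxy1 <- -sum(P[pos] * log2(pxy[pos]))
  hxy2 <- -sum(xlog2x(pxy))
  out["GLCM_InformationalMeasureCorrelation1"] <-
    if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  out["GLCM_InformationalMeasureCorrelation2"] <-
    sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  out
}

# Maximal correlation coefficient: square root of the second-largest
# eigenvalue of Q(i,j) = sum_k p(i,k) p(j,k) / (px_i py_k), restricted to
# occupied gray levels; eigenvalues are clipped to [0, 1] to absorb
# numerical noise. One occupied level -> 1 by convention.
.glcmMCC <- function(P, px, py) {
  keep <- px > 0
  if (sum(keep) < 2L) return(1)
  Pk <- P[keep, keep, drop = FALSE]
  pxk <- px[keep]; pyk <- py[keep]
  ## Q(i,j) = sum_k Pk[i,k] * Pk[j,k] / (pxk[i] * pyk[k])
  A <- Pk / pxk                 # rows scaled by 1/px_i
  B <- t(Pk) / pyk              # B[k, j] = P[j, k] / py_k
  Q <- A %*% B
  ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  lambda2 <- if (length(ev) >= 2L) ev[2L] else 0
  sqrt(min(1, max(0, lambda2)))
}

# Shared calculator for the run-length (GLRLM) and size-zone (GLSZM)
# families, which use identical functional forms over (gray level, size).
# Computed from nonzero triplets (i = gray level 1-based, j = run length /
# zone size, cnt = multiplicity): zone sizes can reach the pixel count, so
# dense level-by-size weight matrices would be enormous.
.rlszTriplets <- function(i, j, cnt, nPixels, prefix) {
  Ns <- sum(cnt)
  nm <- featureNames(prefix)
  out <- stats::setNames(numeric(length(nm)), nm)
  if (Ns == 0) return(out)
  p <- cnt / Ns
  gmarg <- as.vector(rowsum(cnt, i))
  smarg <- as.vector(rowsum(cnt, j))
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  vals <- c(
    sum(p / j^2), sum(p * j^2),
    sum(gmarg^2) / Ns, sum((gmarg / Ns)^2),
    sum(smarg^2) / Ns, sum((smarg / Ns)^2),
    Ns / nPixels,
    sum(p * (i - mu_i)^2), sum(p * (j - mu_j)^2),
    -sum(xlog2x(p)),
    sum(p / i^2), sum(p * i^2),
    sum(p / (i^2 * j^2)), sum(p * i^2 / j^2),
    sum(p * j^2 / i^2), sum(p * i^2 * j^2))
  out[] <- vals
  out
}

.rlszFeatures <- function(counts, nPixels, prefix) {
  nz <- which(counts > 0, arr.ind = TRUE)
  .rlszTriplets(nz[, 1L], nz[, 2L], counts[nz], nPixels, prefix)
}

.gldmFeatures <- function(counts, nPixels) {
  Nz <- sum(counts)
  nm <- featureNames("GLDM")
  out <- stats::setNames(numeric(length(nm)), nm)
  if (Nz == 0) return(out)
  nz <- which(counts > 0, arr.ind = TRUE)
  i <- nz[, 1L]; j <- nz[, 2L]                    # j = dependence + 1
  p <- counts[nz] / Nz
  gmarg <- rowSums(counts); dmarg <- colSums(counts)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  out["GLDM_SmallDependenceEmphasis"] <- sum(p / j^2)
  out["GLDM_LargeDependenceEmphasis"] <- sum(p * j^2)
  out["GLDM_GrayLevelNonUniformity"] <- sum(gmarg^2) / Nz
  out["GLDM_GrayLevelNonUniformityNormalized"] <- sum((gmarg / Nz)^2)
  out["GLDM_DependenceNonUniformity"] <- sum(dmarg^2) / Nz
  out["GLDM_DependenceNonUniformityNormalized"] <- sum((dmarg / Nz)^2)
  out["GLDM_GrayLevelVariance"] <- sum(p * (i - mu_i)^2)
  out["GLDM_DependenceVariance"] <- sum(p * (j - mu_j)^2)
  out["GLDM_DependenceEntropy"] <- -sum(xlog2x(p))
  out["GLDM_LowGrayLevelEmphasis"] <- sum(p / i^2)
  out["GLDM_HighGrayLevelEmphasis"] <- sum(p * i^2)
  out["GLDM_SmallDependenceLowGrayLevelEmphasis"] <- sum(p / (i^2 * j^2))
  out["GLDM_SmallDependenceHighGrayLevelEmphasis"] <- sum(p * i^2 / j^2)
  out["GLDM_LargeDependenceLowGrayLevelEmphasis"] <- sum(p * j^2 / i^2)
  out["GLDM_LargeDependenceHighGrayLevelEmphasis"] <- sum(p * i^2 * j^2)
  out
}

.COARSENESS_CAP <- 1e6

.ngtdmFeatures <- function(tab) {
  n_i <- tab[, "n"]; p_i <- tab[, "p"]; s_i <- tab[, "s"]
  N <- sum(n_i)
  lev <- seq_len(nrow(tab))
  occ <- p_i > 0
  ngp <- sum(occ)
  nm <- featureNames("NGTDM")
  out <- stats::setNames(numeric(length(nm)), nm)
  ps <- sum(p_i * s_i)
  out["NGTDM_Coarseness"] <- if (ps > 0) min(1 / ps, .COARSENESS_CAP)
                             else .COARSENESS_CAP
  if (ngp > 1L) {
    io <- lev[occ]; po <- p_i[occ]; so <- s_i[occ]
    dd <- outer(io, io, "-")^2
    out["NGTDM_Contrast"] <- sum(outer(po, po) * dd) /
      (ngp * (ngp - 1)) * sum(so) / N
    ip <- io * po
    busyDen <- sum(abs(outer(ip, ip, "-")))
    out["NGTDM_Busyness"] <- if (busyDen > 0) ps / busyDen else 0
    psum <- outer(po, po, "+")
    pssum <- outer(po * so, po * so, "+")
    out["NGTDM_Complexity"] <- sum(abs(outer(io, io, "-")) * pssum / psum) / N
    ssum <- sum(so)
    out["NGTDM_Strength"] <- if (ssum > 0) sum(psum * dd) / ssum else 0
  }
  out
}

#' Compute the registry features of one texture matrix
#'
#' Dispatches on the matrix family and returns that family's full named
#' feature set (24 GLCM / 16 GLSZM / 16 GLRLM / 15 GLDM / 5 NGTDM values).
#' Degenerate matrices yield the documented degenerate-limit values and
#' never NaN.
#'
#' @param m A \code{\linkS4class{TextureMatrix}}.
#' @return Named numeric vector in registry order for the family.
#' @export
featuresFromMatrix <- function(m) {
  switch(m@family,
    GLCM = .glcmFeatures(m@table),
    GLRLM = .rlszFeatures(m@table, m@nPixels, "GLRLM"),
    GLSZM = .rlszFeatures(m@table, m@nPixels, "GLSZM"),
    GLDM = .gldmFeatures(m@table, m@nPixels),
    NGTDM = .ngtdmFeatures(m@table),
    stop("unknown family: ", m@family, call. = FALSE))
}
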