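# Synthetic feature tables with planted class-separating features, used to
# probe the selectors and the classifier without running image extraction.

# Planted features get independent class-mean shifts of `shiftSd` pooled
# standard deviations; all other registry features are pure noise.
makePlantedTable <- function(seed, nPerClass = 100L,
                             planted = c("GLCM_Contrast",
                                         "GLSZM_LargeAreaEmphasis",
                                         "GLRLM_RunEntropy",
                                         "NGTDM_Busyness"),
                             features = featureNames(), shiftSd = 2,
                             noiseSd = 0.5, baseMean = 1) {
  set.seed(seed)
  n <- 2L * nPerClass
  labels <- rep(c("control", "remodeled"), each = nPerClass)
  mat <- matrix(rnorm(length(features) * n, baseMean, noiseSd),
                nrow = length(features),
                dimnames = list(features, sprintf("s%03d", seq_len(n))))
  for (f in planted)
    mat[f, labels == "remodeled"] <- mat[f, labels == "remodeled"] +
      shiftSd * noiseSd
  textureExperiment(mat, labels)
}

# A two-feature table that is linearly separable along one planted feature.
makeSeparableTable <- function(seed, nPerClass = 20L) {
  set.seed(seed)
  n <- 2L * nPerClass
  labels <- rep(c("control", "remodeled"), each = nPerClass)
  mat <- matrix(rnorm(2L * n, 0, 0.1), nrow = 2L,
                dimnames = list(c("FOS_Mean", "FOS_Variance"), NULL))
  mat["FOS_Mean", labels == "remodeled"] <- mat["FOS_Mean",
                                                labels == "remodeled"] + 10
  textureExperiment(mat, labels)
}

# Gradient-orientation circular concentration: magnitude-weighted resultant
# length of the doubled gradient angles (1 = perfectly aligned texture,
# 0 = isotropic). Used to verify the phantom generator's orientation field.
orientationConcentration <- function(img) {
  m <- matrix(as.double(img), nrow(img), ncol(img))
  gx <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  gx <- gx[-nrow(gx), , drop = FALSE]
  gy <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  gy <- gy[, -ncol(gy), drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  keep <- mag > 1e-6
  theta <- atan2(gy[keep], gx[keep])
  wts <- mag[keep]
  Mod(sum(wts * exp(2i * theta))) / sum(wts)
}
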