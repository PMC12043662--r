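qi <- function(lv, nL) new("QuantizedImage", levels = lv,
                           nLevels = as.integer(nL),
                           binEdges = seq(0, 256, length.out = nL + 1))

test_that("first-order statistics match closed forms and the degeneracy convention", {
  expect_equal(computeFOS(matrix(7L, 3, 3)),
               c(FOS_Mean = 7, FOS_Variance = 0, FOS_Skewness = 0,
                 FOS_Kurtosis = 0))
  two <- computeFOS(matrix(as.integer(c(0, 0, 255, 255)), 2, 2))
  expect_equal(two[["FOS_Mean"]], 127.5)
  expect_equal(two[["FOS_Variance"]], 16256.25)
  # a symmetric histogram has zero skewness
  sym <- computeFOS(matrix(as.integer(c(10, 20, 30, 20, 10, 30)), 2, 3))
  expect_lt(abs(sym[["FOS_Skewness"]]), 1e-9)
})

test_that("constant-image features take the documented degenerate values", {
  q <- qi(matrix(3L, 6, 6), 8L)
  gf <- featuresFromMatrix(glcm(q, 0))
  expect_equal(gf[["GLCM_JointEntropy"]], 0)
  expect_equal(gf[["GLCM_Contrast"]], 0)
  expect_equal(gf[["GLCM_MaximumProbability"]], 1)
  expect_equal(gf[["GLCM_Correlation"]], 1)
  expect_equal(gf[["GLCM_MaximalCorrelationCoefficient"]], 1)
  expect_equal(gf[["GLCM_JointEnergy"]], 1)
  nf <- featuresFromMatrix(ngtdm(q))
  expect_equal(nf[["NGTDM_Busyness"]], 0)
  expect_equal(nf[["NGTDM_Coarseness"]], 1e6)   # zero-denominator cap
  expect_true(all(is.finite(c(gf, nf))))
})

test_that("GLCM Contrast equals the brute-force cell sum on the reference image", {
  lv <- matrix(as.integer(c(0, 0, 1, 1,
                            0, 0, 1, 1,
                            0, 2, 2, 2,
                            2, 2, 3, 3)), 4, 4, byrow = TRUE)
  m <- glcm(qi(lv, 4L), 0)
  P <- matrixTable(m)
  ref <- 0
  for (i in 1:4) for (j in 1:4) ref <- ref + P[i, j] * (i - j)^2
  expect_equal(featuresFromMatrix(m)[["GLCM_Contrast"]], ref)
})

test_that("GLCM features agree with naive dense-formula evaluation on random images", {
  naiveGLCM <- function(P) {
    nG <- nrow(P)
    i <- matrix(seq_len(nG), nG, nG); j <- t(i)
    px <- rowSums(P); py <- colSums(P)
    mux <- sum(i * P); muy <- sum(j * P)
    list(
      Autocorrelation = sum(i * j * P),
      Contrast = sum((i - j)^2 * P),
      JointEntropy = -sum(ifelse(P > 0, P * log2(P), 0)),
      SumSquares = sum((i - mux)^2 * P),
      InverseVariance = sum(ifelse(i != j, P / (i - j)^2, 0)),
      Correlation = (sum(i * j * P) - mux * muy) /
        sqrt(sum((i - mux)^2 * P) * sum((j - muy)^2 * P)))
  }
  for (seed in 1:10) {
    q <- randomQuantized(seed + 100, maxDim = 8L, nL = 5L)
    m <- glcm(q, 45)
    f <- featuresFromMatrix(m)
    ref <- naiveGLCM(matrixTable(m))
    for (nm in names(ref))
      expect_equal(f[[paste0("GLCM_", nm)]], ref[[nm]], tolerance = 1e-10,
                   label = paste("GLCM", nm, "seed", seed))
  }
})

test_that("run-length features follow their weighted-sum definitions", {
  # rows [0,0,1,1] and [2,2,2,2]: runs (0,2) (1,2) (2,4) horizontally
  lv <- matrix(as.integer(c(0, 0, 1, 1,
                            2, 2, 2, 2)), 2, 4, byrow = TRUE)
  f <- featuresFromMatrix(glrlm(qi(lv, 3L), 0))
  # 3 runs: SRE = mean of 1/len^2; LRE = mean of len^2 (uniform weights)
  expect_equal(f[["GLRLM_ShortRunEmphasis"]], (1 / 4 + 1 / 4 + 1 / 16) / 3)
  expect_equal(f[["GLRLM_LongRunEmphasis"]], (4 + 4 + 16) / 3)
  expect_equal(f[["GLRLM_RunPercentage"]], 3 / 8)
  expect_equal(f[["GLRLM_RunEntropy"]], log2(3))
  expect_equal(f[["GLRLM_HighGrayLevelRunEmphasis"]], (1 + 4 + 9) / 3)
})

test_that("NGTDM features match a direct evaluation of their definitions", {
  m <- matrix(0L, 3, 3); m[2, 2] <- 1L
  tb <- matrixTable(ngtdm(qi(m, 2L)))
  f <- featuresFromMatrix(ngtdm(qi(m, 2L)))
  p <- tb[, "p"]; s <- tb[, "s"]; lev <- 1:2; N <- 9
  expect_equal(f[["NGTDM_Coarseness"]], 1 / sum(p * s))
  expect_equal(f[["NGTDM_Contrast"]],
               (p[1] * p[2] * (1 - 2)^2 * 2 / (2 * 1)) * sum(s) / N)
  expect_equal(f[["NGTDM_Busyness"]],
               sum(p * s) / (2 * abs(1 * p[1] - 2 * p[2])))
  expect_true(all(is.finite(f)))
})
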