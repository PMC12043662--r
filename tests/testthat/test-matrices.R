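qi <- function(lv, nL) new("QuantizedImage", levels = lv,
                           nLevels = as.integer(nL),
                           binEdges = seq(0, 256, length.out = nL + 1))

test_that("quantization maps 8-bit values into equal-width level bins", {
  m <- matrix(as.integer(c(0, 128, 255, 64)), 2, 2)
  expect_identical(levelMap(quantizeImage(m, 256L)), m)        # identity
  expect_equal(levelMap(quantizeImage(matrix(255L, 2, 2), 64L))[1, 1], 63L)
  expect_equal(levelMap(quantizeImage(matrix(128L, 2, 2), 4L))[1, 1], 2L)
  expect_error(quantizeImage(m, 1L), "out of range")
  expect_error(quantizeImage(m, 300L), "out of range")
  expect_error(quantizeImage(matrix(-1L, 2, 2), 8L), "0, 255")
})

test_that("GLCM matches hand-enumerated counts and degenerate limits", {
  lv <- matrix(as.integer(c(0, 0, 1, 1,
                            0, 0, 1, 1,
                            0, 2, 2, 2,
                            2, 2, 3, 3)), 4, 4, byrow = TRUE)
  g <- glcm(qi(lv, 4L), 0, normalize = FALSE)
  expect_equal(sum(matrixTable(g)), 24)       # 12 horizontal pairs x 2
  expect_equal(matrixTable(g)[1, 1], 4)
  expect_true(isSymmetric(matrixTable(g)))
  # normalized table sums to 1
  gp <- glcm(qi(lv, 4L), 0)
  expect_equal(sum(matrixTable(gp)), 1, tolerance = 1e-12)
  # constant image: single diagonal cell with probability 1
  cm <- glcm(qi(matrix(2L, 3, 3), 4L), 45)
  expect_equal(matrixTable(cm)[3, 3], 1)
  expect_equal(sum(matrixTable(cm)), 1)
  # 1 x N image has no vertical pairs
  deg <- glcm(qi(matrix(c(0L, 1L, 0L), 1, 3), 2L), 90)
  expect_true(isDegenerate(deg))
  expect_true(all(matrixTable(deg) == 0))
  expect_error(glcm(qi(lv, 4L), 30), "direction")
})

test_that("GLRLM counts maximal runs per direction", {
  lv <- matrix(as.integer(c(0, 0, 1, 1,
                            2, 2, 2, 2)), 2, 4, byrow = TRUE)
  r <- matrixTable(glrlm(qi(lv, 3L), 0))
  expect_equal(r[1, 2], 1)   # one run (0,0)
  expect_equal(r[2, 2], 1)   # one run (1,1)
  expect_equal(r[3, 4], 1)   # one run of four 2s
  expect_equal(sum(r * rep(seq_len(ncol(r)), each = nrow(r))), 8) # pixels
  # constant NxN image scanned horizontally: N runs of length N
  cN <- matrixTable(glrlm(qi(matrix(1L, 5, 5), 2L), 0))
  expect_equal(cN[2, 5], 5)
  expect_equal(sum(cN), 5)
  # strictly alternating row: all runs have length 1
  alt <- matrixTable(glrlm(qi(matrix(c(0L, 1L, 0L, 1L), 1, 4), 2L), 0))
  expect_equal(ncol(alt), 1L)
  expect_equal(sum(alt), 4)
})

test_that("GLSZM counts connected zones under both connectivities", {
  lv <- matrix(as.integer(c(0, 0, 1,
                            0, 1, 1,
                            2, 2, 2)), 3, 3, byrow = TRUE)
  z <- matrixTable(glszm(qi(lv, 3L)))
  expect_equal(z[, 3], c(1, 1, 1))    # three zones, each of size 3
  expect_equal(sum(z), 3)
  # constant image: a single zone covering all pixels
  zc <- matrixTable(glszm(qi(matrix(0L, 4, 4), 2L)))
  expect_equal(zc[1, 16], 1)
  expect_equal(sum(zc), 1)
  # checkerboard under 4-connectivity: every zone is a single pixel
  cb <- matrix(as.integer((row(matrix(0, 4, 4)) +
                             col(matrix(0, 4, 4))) %% 2), 4, 4)
  z4 <- matrixTable(glszm(qi(cb, 2L), connectivity = 4L))
  expect_equal(ncol(z4), 1L)
  expect_equal(sum(z4), 16)
  # ... but under 8-connectivity the two colors form two zones
  z8 <- matrixTable(glszm(qi(cb, 2L), connectivity = 8L))
  expect_equal(z8[1, 8], 1)
  expect_equal(z8[2, 8], 1)
})

test_that("GLDM dependence counting covers corners, edges and saturation", {
  d <- matrixTable(gldm(qi(matrix(5L, 4, 4), 8L), 0L, 1L))
  expect_equal(d[6, 4], 4)    # corners: 3 equal neighbors
  expect_equal(d[6, 6], 8)    # edges: 5
  expect_equal(d[6, 9], 4)    # interior: 8
  # all levels distinct: every pixel has dependence 0
  lv <- matrix(0:8, 3, 3)
  storage.mode(lv) <- "integer"
  d0 <- matrixTable(gldm(qi(lv, 9L), 0L))
  expect_equal(sum(d0[, 1]), 9)
  # alpha >= nLevels saturates: dependence = neighbor count
  ds <- matrixTable(gldm(qi(lv, 9L), alpha = 9L))
  expect_equal(sum(ds[, 4]), 4)   # corners have 3 neighbors
  expect_equal(sum(ds[, 9]), 1)   # center has 8
})

test_that("NGTDM stores per-level counts, probabilities and differences", {
  tb <- matrixTable(ngtdm(qi(matrix(7L, 4, 4), 8L)))
  expect_true(all(tb[, "s"] == 0))
  expect_equal(sum(tb[, "n"]), 16)
  expect_equal(sum(tb[, "p"]), 1)
  # single bright center pixel in zeros
  m <- matrix(0L, 3, 3); m[2, 2] <- 1L
  t2 <- matrixTable(ngtdm(qi(m, 2L)))
  expect_equal(unname(t2[2, "s"]), 1)
  expect_equal(unname(t2[1, "s"]), 4 * (1 / 3) + 4 * (1 / 5),
               tolerance = 1e-12)
  # swapping the two levels swaps the table rows
  sw <- matrixTable(ngtdm(qi(1L - m, 2L)))
  expect_equal(sw[c(2, 1), ], t2, ignore_attr = TRUE)
})

test_that("all five builders agree with brute-force enumeration on random images", {
  for (seed in 1:25) {
    q <- randomQuantized(seed, maxDim = 8L, nL = 4L)
    lv <- levelMap(q)
    for (d in c(0, 45, 90, 135)) {
      expect_equal(matrixTable(glcm(q, d, normalize = FALSE)),
                   oracleGLCM(lv, 4L, d), ignore_attr = TRUE)
      got <- matrixTable(glrlm(q, d)); ref <- oracleGLRLM(lv, 4L, d)
      k <- max(ncol(got), ncol(ref))
      expect_equal(padCols(got, k), padCols(ref, k), ignore_attr = TRUE)
    }
    for (conn in c(4L, 8L)) {
      got <- matrixTable(glszm(q, conn)); ref <- oracleGLSZM(lv, 4L, conn)
      k <- max(ncol(got), ncol(ref))
      expect_equal(padCols(got, k), padCols(ref, k), ignore_attr = TRUE)
    }
    gotD <- matrixTable(gldm(q)); refD <- oracleGLDM(lv, 4L)
    k <- max(ncol(gotD), ncol(refD))
    expect_equal(padCols(gotD, k), padCols(refD, k), ignore_attr = TRUE)
    expect_equal(matrixTable(ngtdm(q)), oracleNGTDM(lv, 4L),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})
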